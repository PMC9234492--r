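test_that("CBC design construction is balanced, duplicate-free and seeded", {
  d <- build_design(seed = 1)
  expect_equal(nrow(d$profiles), 12 * 4)
  expect_equal(nrow(d$X), 12 * 5)          # opt-out row per task
  # no task contains two identical profiles
  key <- do.call(paste, d$profiles[names(d$attributes)])
  expect_false(any(duplicated(data.frame(d$profiles$task, key))))
  # approximate level balance: each material level close to 12 appearances
  tab <- table(d$profiles$material)
  expect_true(all(tab >= 8 & tab <= 16))
  expect_identical(build_design(seed = 5)$profiles,
                   build_design(seed = 5)$profiles)

  # a single 2-level attribute with 2 alternatives forces both levels per task
  d2 <- build_design(list(x = c("lo", "hi")), n_tasks = 6,
                     n_alternatives = 2, opt_out = FALSE, seed = 2)
  per_task <- tapply(d2$profiles$x, d2$profiles$task,
                     function(v) length(unique(v)))
  expect_true(all(per_task == 2))

  expect_error(build_design(list(x = c("a", "b")), n_alternatives = 3,
                            opt_out = FALSE, seed = 1), "distinct profiles")
})

test_that("MNL log-likelihood has the softmax form and logit invariance", {
  d <- build_design(seed = 1)
  p <- ncol(d$X)
  cd <- generate_choice_data(d, rep(0, p), 0, 1, seed = 2)
  expect_equal(mnl_loglik(rep(0, p), cd), 12 * log(1 / 5))

  # adding a constant utility to every alternative of each set changes nothing
  withr::with_seed(3, beta <- rnorm(p, sd = 0.5))
  cd_const <- cd
  cd_const$X <- cbind(cd$X, const = 1)
  expect_equal(mnl_loglik(c(beta, 0), cd_const),
               mnl_loglik(c(beta, 3.7), cd_const), tolerance = 1e-10)

  expect_error(mnl_loglik(rep(0, p - 1), cd), "length")
})

test_that("analytic MNL score matches finite differences", {
  d <- build_design(seed = 4)
  p <- ncol(d$X)
  cd <- generate_choice_data(d, rep(0, p), 0.3, 5, seed = 5)
  withr::with_seed(6, beta <- rnorm(p, sd = 0.4))
  score <- cgpfield:::mnl_score_info(beta, cd)$score
  eps <- 1e-6
  fd <- vapply(seq_len(p), function(j) {
    e <- numeric(p); e[j] <- eps
    (mnl_loglik(beta + e, cd) - mnl_loglik(beta - e, cd)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(score), fd, tolerance = 1e-5)
})

test_that("pooled MNL is consistent on homogeneous synthetic data", {
  d <- build_design(seed = 7)
  p <- ncol(d$X)
  truth <- setNames(rep(0, p), colnames(d$X))
  truth["material.GM_bioplastic"] <- 0.8
  truth["opt_out"] <- -0.5
  cd <- generate_choice_data(d, truth, 0, 300, seed = 8)
  fit <- fit_pooled_mnl(cd)
  expect_true(fit$converged)
  expect_true(all(abs(fit$estimate - truth) <= 3 * fit$se))
  # likelihood at the optimum dominates the truth
  expect_gte(fit$loglik, mnl_loglik(truth, cd) - 1e-8)

  # symmetric 50/50 two-option data pulls the coefficient to zero
  d2 <- build_design(list(x = c("lo", "hi")), n_tasks = 12,
                     n_alternatives = 2, opt_out = FALSE, seed = 9)
  cd2 <- generate_choice_data(d2, 0, 0, 200, seed = 10)
  fit2 <- fit_pooled_mnl(cd2)
  expect_lt(abs(fit2$estimate), 3 * fit2$se)
})

test_that("HB-MNL recovers a known population part-worth", {
  d <- build_design(seed = 21)
  p <- ncol(d$X)
  mu <- setNames(rep(0, p), colnames(d$X))
  mu["material.GM_bioplastic"] <- 0.8
  cd <- generate_choice_data(d, mu, 0.5, 200, seed = 22)
  post <- fit_hb_mnl(cd, n_iter = 1500, burn_in = 750, seed = 23)
  s <- summarize_partworth(post, "material.GM_bioplastic")
  expect_lt(abs(s$mean - 0.8), 0.2)
  expect_true(s$sign_significant)
  expect_gt(s$lower, 0)
  # MH acceptance after adaptation within the usable band
  expect_gt(post$acceptance_rate, 0.1)
  expect_lt(post$acceptance_rate, 0.6)
  # reproducibility by seed
  post2 <- fit_hb_mnl(cd, n_iter = 300, burn_in = 150, seed = 29)
  post3 <- fit_hb_mnl(cd, n_iter = 300, burn_in = 150, seed = 29)
  expect_identical(post2$mu, post3$mu)
})

test_that("HB-MNL credible intervals cover zero on zero-signal data", {
  d <- build_design(seed = 31)
  p <- ncol(d$X)
  cd <- generate_choice_data(d, rep(0, p), 0.3, 150, seed = 32)
  post <- fit_hb_mnl(cd, n_iter = 1200, burn_in = 600, seed = 33)
  for (el in post$parameters) {
    s <- summarize_partworth(post, el)
    expect_false(s$sign_significant)
  }
  expect_error(summarize_partworth(post, "nope"), "unknown parameter")
})

test_that("HB population mean collapses to the pooled fit without heterogeneity", {
  d <- build_design(seed = 41)
  p <- ncol(d$X)
  mu <- setNames(rep(0, p), colnames(d$X))
  mu["material.GM_bioplastic"] <- 0.6
  cd <- generate_choice_data(d, mu, 0.01, 200, seed = 42)
  pooled <- fit_pooled_mnl(cd)
  post <- fit_hb_mnl(cd, n_iter = 1200, burn_in = 600, seed = 43)
  pm <- colMeans(post$mu)
  psd <- apply(post$mu, 2, sd)
  expect_true(all(abs(pm - pooled$estimate) <= 2 * psd + 2 * pooled$se))
})
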