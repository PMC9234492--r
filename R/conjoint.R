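#' Default food-wrapping attribute set
#'
#' The wrapping-material choice experiment combines the material
#' (conventional petroleum plastic, recycled paper, GM bioplastic from
#' transgenic tobacco, natural leaf) with an antibacterial functionality,
#' an environmental certification and a surcharge. Surcharge levels are not
#' fully enumerated in the source and are exposed as configuration.
#'
#' @return named list of level vectors.
#' @export
default_wrapping_attributes <- function() {
  list(material = c("conventional", "paper", "GM_bioplastic", "natural"),
       functionality = c("none", "antibacterial"),
       certification = c("none", "eco_certified"),
       surcharge = c("0%", "5%", "10%", "20%"))
}

#' Choice-based-conjoint design
#'
#' Builds a randomized, approximately level-balanced design: `n_tasks`
#' choice tasks of `n_alternatives` full profiles each (plus an opt-out when
#' enabled), no task containing two identical profiles. Level balance is
#' achieved by dealing each attribute's levels evenly over the
#' `n_tasks * n_alternatives` profile slots before shuffling; duplicate
#' profiles within a task are repaired by redrawing.
#'
#' @param attributes named list of level vectors (>= 2 levels each).
#' @param n_tasks number of choice tasks per respondent (default 12).
#' @param n_alternatives full profiles per task (default 4).
#' @param opt_out add a no-choice alternative to every task (default `TRUE`).
#' @param coding `"effects"` (last level as reference, coded -1) or
#'   `"dummy"`.
#' @param seed integer seed.
#' @return an object of class `cbc_design`: `attributes`, `n_tasks`,
#'   `n_alternatives`, `opt_out`, `coding`, `profiles` (data frame of
#'   task/alt/levels) and the coded model matrix `X` (one row per
#'   task-alternative, opt-out rows included).
#' @export
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d$X)  # 12 * 5
build_design <- function(attributes = default_wrapping_attributes(),
                         n_tasks = 12, n_alternatives = 4, opt_out = TRUE,
                         coding = c("effects", "dummy"), seed = NULL) {
  coding <- match.arg(coding)
  stop_if_not_count(n_tasks, "n_tasks")
  stop_if_not_count(n_alternatives, "n_alternatives", min = 2L)
  if (!is.list(attributes) || is.null(names(attributes)) ||
      any(vapply(attributes, length, integer(1)) < 2))
    stop("attributes must be a named list with >= 2 levels each",
         call. = FALSE)
  n_profiles_possible <- prod(vapply(attributes, length, integer(1)))
  if (n_profiles_possible < n_alternatives)
    stop("cannot fill a task with distinct profiles: too few level ",
         "combinations", call. = FALSE)
  slots <- n_tasks * n_alternatives
  profiles <- with_seed(seed, {
    prof <- data.frame(task = rep(seq_len(n_tasks), each = n_alternatives),
                       alt = rep(seq_len(n_alternatives), n_tasks))
    for (a in names(attributes))
      prof[[a]] <- sample(rep(attributes[[a]],
                              length.out = slots))
    # repair within-task duplicate profiles by redrawing the later row
    key <- function(d) do.call(paste, c(d[names(attributes)], sep = "\r"))
    for (tries in 1:1000) {
      dup <- duplicated(data.frame(task = prof$task, k = key(prof)))
      if (!any(dup)) break
      for (i in which(dup))
        for (a in names(attributes))
          prof[[a]][i] <- sample(attributes[[a]], 1)
    }
    if (any(duplicated(data.frame(task = prof$task, k = key(prof)))))
      stop("could not construct duplicate-free tasks", call. = FALSE)
    prof
  })
  design <- structure(list(attributes = attributes,
                           n_tasks = as.integer(n_tasks),
                           n_alternatives = as.integer(n_alternatives),
                           opt_out = isTRUE(opt_out), coding = coding,
                           profiles = profiles),
                      class = "cbc_design")
  design$X <- code_design(design)
  design
}

#' Code a CBC design into a model matrix
#'
#' Effects coding represents an attribute with L levels as L-1 columns, the
#' last level coded -1 on all of them; dummy coding uses 0/1 indicators
#' against the first level. The opt-out alternative carries zeros on every
#' attribute column and its own alternative-specific constant `opt_out`.
#'
#' @param design a `cbc_design`.
#' @return numeric matrix, one row per task-alternative (opt-out rows last
#'   within each task when enabled), with attributes `task` and `alt`.
#' @export
code_design <- function(design) {
  stopifnot(inherits(design, "cbc_design"))
  prof <- design$profiles
  blocks <- lapply(names(design$attributes), function(a) {
    lv <- design$attributes[[a]]
    L <- length(lv)
    f <- factor(prof[[a]], levels = lv)
    if (design$coding == "effects") {
      m <- matrix(0, nrow(prof), L - 1,
                  dimnames = list(NULL, paste(a, lv[-L], sep = ".")))
      for (l in seq_len(L - 1)) m[f == lv[l], l] <- 1
      m[f == lv[L], ] <- -1
    } else {
      m <- matrix(0, nrow(prof), L - 1,
                  dimnames = list(NULL, paste(a, lv[-1], sep = ".")))
      for (l in 2:L) m[f == lv[l], l - 1] <- 1
    }
    m
  })
  X <- do.call(cbind, blocks)
  task <- prof$task; alt <- prof$alt
  if (design$opt_out) {
    Xo <- matrix(0, design$n_tasks, ncol(X))
    X <- rbind(X, Xo)
    X <- cbind(X, opt_out = c(rep(0, nrow(prof)), rep(1, design$n_tasks)))
    task <- c(task, seq_len(design$n_tasks))
    alt <- c(alt, rep(design$n_alternatives + 1L, design$n_tasks))
    ord <- order(task, alt)
    X <- X[ord, , drop = FALSE]
    task <- task[ord]; alt <- alt[ord]
  }
  attr(X, "task") <- task
  attr(X, "alt") <- alt
  X
}

#' @export
print.cbc_design <- function(x, ...) {
  cat(sprintf(
    "CBC design: %d tasks x %d alternatives%s, %s coding, %d parameters\n",
    x$n_tasks, x$n_alternatives, if (x$opt_out) " + opt-out" else "",
    x$coding, ncol(x$X)))
  invisible(x)
}

#' Generate synthetic choice data from a multinomial logit
#'
#' Draws each respondent's part-worth vector from a multivariate normal
#' population and each choice from the multinomial logit over the task's
#' alternatives (plus opt-out), using the Gumbel-max construction.
#'
#' @param design a `cbc_design` from [build_design()].
#' @param population_mean numeric vector of population mean part-worths,
#'   length `ncol(design$X)` (optionally named like its columns).
#' @param population_cov population covariance matrix (symmetric PSD) of the
#'   same dimension; a scalar is expanded to `scalar^2 * I` interpreted as a
#'   common standard deviation.
#' @param n_respondents number of respondents.
#' @param seed integer seed.
#' @return an object of class `choice_data`: `design`, `X` (stacked coded
#'   rows for all respondents), `respondent`, `task`, `alt`, `chosen`
#'   (logical), `set_id`, `true_betas` (the simulated part-worths), `df`
#'   (long-format data frame).
#' @export
generate_choice_data <- function(design, population_mean, population_cov,
                                 n_respondents, seed = NULL) {
  stopifnot(inherits(design, "cbc_design"))
  stop_if_not_count(n_respondents, "n_respondents")
  p <- ncol(design$X)
  if (length(population_mean) != p)
    stop(sprintf("population mean has length %d but the design codes %d ",
                 length(population_mean), p), "parameters", call. = FALSE)
  if (length(population_cov) == 1)
    population_cov <- diag(as.numeric(population_cov)^2, p)
  if (!isTRUE(all.equal(population_cov, t(population_cov))) ||
      any(eigen(population_cov, symmetric = TRUE,
                only.values = TRUE)$values < -1e-8))
    stop("population covariance must be symmetric positive semi-definite",
         call. = FALSE)
  k <- design$n_alternatives + as.integer(design$opt_out)
  with_seed(seed, {
    betas <- MASS::mvrnorm(n_respondents, mu = as.numeric(population_mean),
                           Sigma = population_cov)
    if (n_respondents == 1) betas <- matrix(betas, 1)
    colnames(betas) <- colnames(design$X)
    rows_per_resp <- nrow(design$X)
    resp <- rep(seq_len(n_respondents), each = rows_per_resp)
    X <- design$X[rep(seq_len(rows_per_resp), n_respondents), , drop = FALSE]
    U <- rowSums(X * betas[resp, , drop = FALSE])
    g <- -log(-log(stats::runif(length(U))))  # Gumbel-max sampling
    n_sets <- n_respondents * design$n_tasks
    pick <- max.col(matrix(U + g, nrow = n_sets, byrow = TRUE),
                    ties.method = "first")
    chosen <- rep(FALSE, length(U))
    chosen[(seq_len(n_sets) - 1L) * k + pick] <- TRUE
    structure(list(design = design, X = X,
                   respondent = resp,
                   task = rep(attr(design$X, "task"), n_respondents),
                   alt = rep(attr(design$X, "alt"), n_respondents),
                   chosen = chosen,
                   set_id = rep(seq_len(n_sets), each = k),
                   set_size = k,
                   true_betas = betas),
              class = "choice_data")
  })
}

#' @export
print.choice_data <- function(x, ...) {
  cat(sprintf(
    "Choice data: %d respondents x %d tasks, %d alternatives/task, %d parameters\n",
    max(x$respondent), x$design$n_tasks, x$set_size, ncol(x$X)))
  invisible(x)
}

#' Write choice data as long-format CSV
#'
#' Columns: respondent, task, alternative, the attribute levels (empty for
#' the opt-out row) and a 0/1 chosen flag.
#'
#' @param data a `choice_data` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(data, path) {
  stopifnot(inherits(data, "choice_data"))
  d <- data$design
  prof <- d$profiles
  lev <- as.data.frame(lapply(names(d$attributes), function(a) {
    v <- rep(NA_character_, nrow(d$X))
    m <- match(paste(attr(d$X, "task"), attr(d$X, "alt")),
               paste(prof$task, prof$alt))
    v[!is.na(m)] <- prof[[a]][m[!is.na(m)]]
    v
  }), col.names = names(d$attributes))
  out <- data.frame(respondent = data$respondent, task = data$task,
                    alternative = data$alt,
                    lev[rep(seq_len(nrow(d$X)), max(data$respondent)), ,
                        drop = FALSE],
                    chosen = as.integer(data$chosen))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# per-set log choice probabilities for a utility vector (sets of equal size)
set_logprob <- function(U, data) {
  k <- data$set_size
  Um <- matrix(U, nrow = k)                  # columns = choice sets
  m <- apply(Um, 2, max)
  lse <- m + log(colSums(exp(sweep(Um, 2, m))))
  U[data$chosen] - lse
}

#' Multinomial-logit log-likelihood
#'
#' Sum over choice sets of the log softmax probability of the chosen
#' alternative under a single (pooled) part-worth vector; the opt-out enters
#' through its alternative-specific constant column.
#'
#' @param partworths numeric vector, length `ncol(data$X)`.
#' @param data a `choice_data` object.
#' @return log-likelihood (scalar).
#' @export
#' @examples
#' d <- build_design(seed = 1)
#' cd <- generate_choice_data(d, rep(0, ncol(d$X)), 0, 1, seed = 2)
#' mnl_loglik(rep(0, ncol(d$X)), cd)  # 12 * log(1/5)
mnl_loglik <- function(partworths, data) {
  stopifnot(inherits(data, "choice_data"))
  if (length(partworths) != ncol(data$X))
    stop(sprintf("part-worth vector has length %d, design codes %d",
                 length(partworths), ncol(data$X)), call. = FALSE)
  U <- drop(data$X %*% partworths)
  sum(set_logprob(U, data))
}

# analytic score and information for the pooled MNL (used by Newton)
mnl_score_info <- function(beta, data) {
  U <- drop(data$X %*% beta)
  k <- data$set_size
  Um <- matrix(U, nrow = k)
  m <- apply(Um, 2, max)
  Pm <- exp(sweep(Um, 2, m))
  Pm <- sweep(Pm, 2, colSums(Pm), "/")
  P <- as.vector(Pm)
  y <- as.numeric(data$chosen)
  score <- drop(crossprod(data$X, y - P))
  A <- rowsum(data$X * P, data$set_id)     # per-set E[x]
  info <- crossprod(data$X * sqrt(P)) - crossprod(A)
  list(score = score, info = info, loglik = sum(U[data$chosen]) -
         sum(m + log(colSums(exp(sweep(Um, 2, m))))))
}

#' Fit a pooled multinomial logit by maximum likelihood
#'
#' Newton-Raphson on the analytic score and information; converges on the
#' gradient norm. A baseline ("aggregate") model that ignores respondent
#' heterogeneity.
#'
#' @param data a `choice_data` object.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton steps.
#' @return list of class `mnl_fit`: `estimate` (named), `se`, `vcov`,
#'   `loglik`, `iterations`, `converged`.
#' @export
fit_pooled_mnl <- function(data, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(data, "choice_data"))
  p <- ncol(data$X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    si <- mnl_score_info(beta, data)
    if (rcond(si$info) < 1e-12)
      stop("information matrix is (near-)singular: separation or rank ",
           "deficiency in the coded design", call. = FALSE)
    step <- solve(si$info, si$score)
    # halve the step until the likelihood does not decrease
    for (h in 0:20) {
      cand <- beta + step / 2^h
      if (mnl_loglik(cand, data) >= si$loglik - 1e-10) break
    }
    beta <- cand
    if (sqrt(sum(si$score^2)) < tol) { converged <- TRUE; break }
  }
  si <- mnl_score_info(beta, data)
  vc <- solve(si$info)
  names(beta) <- colnames(data$X)
  structure(list(estimate = beta, se = sqrt(diag(vc)), vcov = vc,
                 loglik = si$loglik, iterations = it,
                 converged = converged),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat(sprintf("Pooled MNL fit (logLik %.3f, %d Newton steps%s)\n", x$loglik,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  print(round(cbind(estimate = x$estimate, se = x$se), 4))
  invisible(x)
}

default_hb_prior <- function(p) {
  list(mu0 = rep(0, p), V0 = diag(100, p),   # weak N(0, 10^2) on the mean
       nu0 = p + 2, S0 = diag(1, p))         # inverse-Wishart on covariance
}

#' Fit a hierarchical Bayesian multinomial logit
#'
#' Respondent-level part-worth vectors are modeled as draws from a
#' multivariate normal population; estimation is by MCMC with conjugate
#' Gibbs updates for the population mean (normal) and covariance
#' (inverse-Wishart, drawn by inverting `stats::rWishart`) and a
#' random-walk Metropolis step for each respondent's part-worths, proposed
#' jointly with covariance proportional to the current population
#' covariance. The scalar proposal step is adapted during burn-in toward
#' ~30% acceptance and frozen afterward.
#'
#' @param data a `choice_data` object.
#' @param prior list with `mu0`, `V0`, `nu0`, `S0` (defaults: mean 0 with
#'   sd-10 normal, inverse-Wishart with `p + 2` degrees of freedom and
#'   identity scale).
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded (and used for step adaptation).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed.
#' @param step_init initial Metropolis step scale.
#' @param keep_respondent_draws store thinned respondent-level draws
#'   (default `TRUE`).
#' @return an object of class `hb_posterior`: `mu` (draws x p matrix),
#'   `Sigma` (p x p x draws array), optional `betas`
#'   (draws x respondents x p), `acceptance_rate` (post burn-in), `step`,
#'   `n_iter`, `burn_in`, `thin`, `seed`, `parameters` (column names).
#' @export
fit_hb_mnl <- function(data, prior = NULL, n_iter = 2000, burn_in = 1000,
                       thin = 1, seed = NULL, step_init = 0.25,
                       keep_respondent_draws = TRUE) {
  stopifnot(inherits(data, "choice_data"), burn_in < n_iter)
  p <- ncol(data$X)
  n <- max(data$respondent)
  if (is.null(prior)) prior <- default_hb_prior(p)
  if (any(eigen(prior$S0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("prior scale matrix S0 must be positive definite", call. = FALSE)
  V0_inv <- solve(prior$V0)
  V0_inv_mu0 <- drop(V0_inv %*% prior$mu0)

  rows_per_resp <- nrow(data$X) / n
  resp_of_row <- data$respondent
  tasks_per_resp <- data$design$n_tasks

  # per-respondent log-likelihood for an n x p matrix of part-worths
  resp_loglik <- function(B) {
    U <- rowSums(data$X * B[resp_of_row, , drop = FALSE])
    lp <- set_logprob(U, data)
    rowsum(lp, rep(seq_len(n), each = tasks_per_resp))[, 1]
  }

  with_seed(seed, {
    B <- matrix(0, n, p)
    mu <- rep(0, p)
    Sigma <- diag(1, p)
    ll <- resp_loglik(B)
    step <- step_init
    n_keep <- floor((n_iter - burn_in) / thin)
    mu_draws <- matrix(NA_real_, n_keep, p,
                       dimnames = list(NULL, colnames(data$X)))
    Sigma_draws <- array(NA_real_, c(p, p, n_keep))
    beta_draws <- if (keep_respondent_draws)
      array(NA_real_, c(n_keep, n, p)) else NULL
    acc_window <- 0; acc_post <- 0; n_post <- 0
    kept <- 0
    for (it in seq_len(n_iter)) {
      # --- Metropolis update of respondent part-worths (joint RW) ---
      Su <- chol(Sigma)
      prop <- B + step * (matrix(stats::rnorm(n * p), n, p) %*% Su)
      ll_prop <- resp_loglik(prop)
      # prior terms: -0.5 (b - mu)' Sigma^{-1} (b - mu)
      qf <- function(M) {
        W <- backsolve(Su, t(sweep(M, 2, mu)), transpose = TRUE)
        colSums(W^2)
      }
      log_acc <- (ll_prop - 0.5 * qf(prop)) - (ll - 0.5 * qf(B))
      acc <- log(stats::runif(n)) < log_acc
      B[acc, ] <- prop[acc, ]
      ll[acc] <- ll_prop[acc]
      acc_rate <- mean(acc)
      if (it <= burn_in) {
        acc_window <- acc_window + acc_rate
        if (it %% 50 == 0) {           # adapt toward ~0.30 acceptance
          step <- step * exp(acc_window / 50 - 0.30)
          step <- min(max(step, 1e-3), 5)
          acc_window <- 0
        }
      } else {
        acc_post <- acc_post + acc_rate; n_post <- n_post + 1
      }
      # --- Gibbs update of the population mean ---
      Sigma_inv <- chol2inv(Su)
      prec <- n * Sigma_inv + V0_inv
      mean_post <- solve(prec, drop(Sigma_inv %*% colSums(B)) + V0_inv_mu0)
      mu <- drop(mean_post + backsolve(chol(prec), stats::rnorm(p)))
      # --- Gibbs update of the population covariance ---
      Bc <- sweep(B, 2, mu)
      S_n <- prior$S0 + crossprod(Bc)
      W <- stats::rWishart(1, prior$nu0 + n, solve(S_n))[, , 1]
      Sigma <- solve(W)
      Sigma <- (Sigma + t(Sigma)) / 2
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1
        mu_draws[kept, ] <- mu
        Sigma_draws[, , kept] <- Sigma
        if (keep_respondent_draws) beta_draws[kept, , ] <- B
      }
    }
    structure(list(mu = mu_draws[seq_len(kept), , drop = FALSE],
                   Sigma = Sigma_draws[, , seq_len(kept), drop = FALSE],
                   betas = if (keep_respondent_draws)
                     beta_draws[seq_len(kept), , , drop = FALSE] else NULL,
                   acceptance_rate = acc_post / max(n_post, 1),
                   step = step, n_iter = n_iter, burn_in = burn_in,
                   thin = thin, seed = seed,
                   parameters = colnames(data$X)),
              class = "hb_posterior")
  })
}

#' @export
print.hb_posterior <- function(x, ...) {
  cat(sprintf(
    "HB-MNL posterior: %d draws (of %d iterations, %d burn-in), MH acceptance %.2f\n",
    nrow(x$mu), x$n_iter, x$burn_in, x$acceptance_rate))
  s <- t(apply(x$mu, 2, function(d)
    c(mean = mean(d), q2.5 = stats::quantile(d, 0.025, names = FALSE),
      q97.5 = stats::quantile(d, 0.975, names = FALSE))))
  print(round(s, 3))
  invisible(x)
}

#' Summarize one population part-worth
#'
#' Posterior mean and equal-tail credible interval for one element of the
#' population mean vector, with a flag that is `TRUE` when the interval
#' excludes zero (the "positive/negative and significant" reading used for
#' choice-experiment utilities).
#'
#' @param posterior an `hb_posterior`.
#' @param element parameter name (a column of the coded design, e.g.
#'   `"material.GM_bioplastic"`).
#' @param level credible level (default 0.95).
#' @return list: `element`, `mean`, `lower`, `upper`, `level`,
#'   `sign_significant`.
#' @export
summarize_partworth <- function(posterior, element, level = 0.95) {
  stopifnot(inherits(posterior, "hb_posterior"))
  if (!element %in% posterior$parameters)
    stop(sprintf("unknown parameter '%s'", element), call. = FALSE)
  d <- posterior$mu[, element]
  a <- (1 - level) / 2
  ci <- stats::quantile(d, c(a, 1 - a), names = FALSE)
  list(element = element, mean = mean(d), lower = ci[1], upper = ci[2],
       level = level, sign_significant = ci[1] > 0 || ci[2] < 0)
}
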