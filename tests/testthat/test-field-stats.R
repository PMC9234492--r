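test_that("test selection gates on normality and homogeneity", {
  # fixture seed chosen so the draws satisfy the gates' preconditions
  # (normal samples that look normal, an exponential that looks skewed)
  withr::with_seed(4, {
    normal <- list(rnorm(100), rnorm(100, 1))
    skewed <- list(rexp(50), rnorm(50))
    hetero <- list(rnorm(100, sd = 1), rnorm(100, sd = 6))
    third <- rnorm(100)
  })
  expect_equal(select_test(normal)$chosen_test, "t_test")
  expect_equal(select_test(skewed)$chosen_test, "wilcoxon")
  expect_equal(select_test(hetero)$chosen_test, "welch_t")
  expect_equal(select_test(c(normal, list(third)))$chosen_test, "anova")

  # the literal printed convention inverts both gates
  expect_equal(select_test(normal, convention = "paper_literal")$chosen_test,
               "wilcoxon")

  expect_error(select_test(list(1:2, 1:5)), "at least 3")
  expect_error(select_test(list(1:5)), "two groups")
})

test_that("group comparison executes the plan two-sided", {
  g <- list(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6))
  plan <- select_test(g)
  res <- compare_groups(g, plan)
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)

  withr::with_seed(2, {
    strong <- list(rnorm(30), rnorm(30, 5))
  })
  res2 <- compare_groups(strong, select_test(strong))
  expect_true(res2$significant)
  expect_lt(res2$p_value, 1e-6)

  # plan built for different data must not run
  expect_error(compare_groups(list(1:5, 1:5, 1:5), plan), "different number")
})

test_that("t-test p-value agrees with a permutation oracle", {
  withr::with_seed(3, {
    a <- rnorm(30)
    b <- rnorm(30, 0.5)
  })
  p_t <- stats::t.test(a, b, var.equal = TRUE)$p.value
  p_perm <- permutation_p(a, b, n_perm = 10000, seed = 4)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("letter display handles the trivial structures", {
  none <- matrix(FALSE, 4, 4)
  expect_equal(unname(letter_display(none)), rep("a", 4))

  all_sig <- !diag(3) > 0
  expect_setequal(unname(letter_display(all_sig)), c("a", "b", "c"))

  chain <- matrix(FALSE, 3, 3); chain[1, 3] <- chain[3, 1] <- TRUE
  expect_equal(unname(letter_display(chain)), c("a", "ab", "b"))

  asym <- matrix(FALSE, 2, 2); asym[1, 2] <- TRUE
  expect_error(letter_display(asym), "symmetric")
})

test_that("letter display encodes exactly the not-different relation (k <= 4)", {
  for (k in 2:4) {
    for (sig in all_flag_matrices(k)) {
      out <- letter_display(sig)
      expect_true(cld_matches_relation(sig, out),
                  info = paste("k =", k, "flags =",
                               paste(sig[upper.tri(sig)], collapse = "")))
    }
  }
})

test_that("pairwise significance matrix feeds the letter display", {
  withr::with_seed(5, {
    g <- list(a = rnorm(25, 0), b = rnorm(25, 0.2), c = rnorm(25, 4))
  })
  plan <- select_test(g)
  sig <- pairwise_significance(g, plan)
  expect_true(isSymmetric(sig))
  expect_false(any(diag(sig)))
  expect_true(sig["a", "c"] && sig["b", "c"] && !sig["a", "b"])
  letters_out <- letter_display(sig)
  expect_equal(unname(letters_out), c("a", "a", "b"))
  # Holm adjustment can only switch flags off, never on
  holm <- pairwise_significance(g, plan, adjust = "holm")
  expect_true(all(holm <= sig))
})

test_that("significance flag equals p <= alpha on every path", {
  withr::with_seed(6, {
    cases <- list(list(rnorm(20), rnorm(20, 2)),    # parametric
                  list(rexp(30), rexp(30) + 2),     # rank
                  list(rnorm(40, sd = 1), rnorm(40, 3, sd = 5))) # Welch
  })
  for (g in cases) {
    plan <- select_test(g)
    res <- compare_groups(g, plan)
    expect_identical(res$significant, res$p_value <= plan$alpha)
  }
})
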