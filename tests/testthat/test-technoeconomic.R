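test_that("triangular sampler honours bounds, moments and seeding", {
  expect_error(triangular_dist(1, 0, 0.5), "min <= mode <= max")

  # degenerate distribution collapses to a constant
  expect_equal(sample_triangular(triangular_dist(2, 2, 2), 50, seed = 1),
               rep(2, 50))

  # symmetric triangle: median at the midpoint
  x <- sample_triangular(triangular_dist(0, 1, 0.5), 1e5, seed = 1)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(median(x) - 0.5), 3 * 0.5 / sqrt(1e5))

  # closed-form mean (a + b + c) / 3 for the extraction-yield triangle
  ey <- triangular_dist(0.55, 0.97, 0.90)
  y <- sample_triangular(ey, 1e5, seed = 2)
  se <- sd(y) / sqrt(1e5)
  expect_lt(abs(mean(y) - (0.55 + 0.97 + 0.90) / 3), 3 * se)

  expect_identical(sample_triangular(ey, 100, seed = 7),
                   sample_triangular(ey, 100, seed = 7))
})

test_that("triangular CDF/quantile are mutually inverse", {
  d <- triangular_dist(0.70, 0.93, 0.90)
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(ptriangular(qtriangular(p, d), d), p, tolerance = 1e-10)
})

test_that("deterministic scenario table reproduces the published bounds", {
  st <- scenario_table(scenario_inputs())
  expect_equal(st$PR, 88)
  expect_equal(unname(unlist(st$display[st$display$quantity == "Y", 2:4])),
               c(0.39, 0.90, 0.81))
  expect_equal(unname(unlist(st$display[st$display$quantity == "E [kg/ha]",
                                        2:4])), c(34, 79, 71))
  # revenue must come from the UNROUNDED extracted mass
  expect_equal(unname(unlist(st$display[st$display$quantity == "R [USD/ha]",
                                        2:4])), c(9317, 43662, 23522))
  expect_false(isTRUE(all.equal(34 * 275, 9317)))  # rounded-first would differ

  zero <- scenario_table(scenario_inputs(C = 0))
  expect_equal(zero$PR, 0)
  expect_equal(unname(zero$E), c(0, 0, 0))
  expect_equal(unname(zero$R), c(0, 0, 0))
})

test_that("Monte Carlo stays inside analytic bounds and matches closed-form means", {
  inp <- scenario_inputs()
  mc <- run_monte_carlo(inp, n_reps = 2e4, seed = 11)
  expect_true(all(mc$E >= 88 * 0.55 * 0.70 & mc$E <= 88 * 0.97 * 0.93))
  expect_true(all(mc$R >= 88 * 0.55 * 0.70 * 275))

  # independence: E[E] = PR E[EY] E[PY]; E[R] adds E[P]
  mean_E <- 88 * mean(c(0.55, 0.97, 0.90)) * mean(c(0.70, 0.93, 0.90))
  mean_R <- mean_E * mean(c(275, 550, 330))
  expect_lt(abs(mean(mc$E) - mean_E), 4 * sd(mc$E) / sqrt(2e4))
  expect_lt(abs(mean(mc$R) - mean_R), 4 * sd(mc$R) / sqrt(2e4))

  # degenerate inputs give a zero-variance output at the scenario mode
  degen <- scenario_inputs(EY = triangular_dist(0.9, 0.9, 0.9),
                           PY = triangular_dist(0.9, 0.9, 0.9),
                           P = triangular_dist(330, 330, 330))
  mcd <- run_monte_carlo(degen, n_reps = 10, seed = 1)
  expect_equal(unname(mcd$summary_E), rep(88 * 0.81, 6))
  expect_equal(unname(mcd$summary_R), rep(88 * 0.81 * 330, 6))
})

test_that("six-number summary follows the Min/1st-Qu/Median/Mean/3rd-Qu/Max layout", {
  expect_equal(unname(summarize_samples(1:5)), c(1, 2, 3, 3, 4, 5))
  expect_equal(unname(summarize_samples(rep(7, 10))), rep(7, 6))
  u <- withr::with_seed(5, runif(1e5))
  s <- summarize_samples(u)
  expect_equal(unname(s[c("q1", "median", "mean", "q3")]),
               c(0.25, 0.5, 0.5, 0.75), tolerance = 0.01)
  expect_error(summarize_samples(numeric(0)), "at least one")
})

test_that("fine-chemical revenue is mass times price", {
  expect_identical(fine_chemical_revenue(60, 3300), 198000)
  expect_identical(fine_chemical_revenue(0, 3300), 0)
  expect_identical(fine_chemical_revenue(88, 275), 24200)
})
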