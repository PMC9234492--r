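test_that("linear calibration fitting recovers exact and noisy lines", {
  conc <- c(0.5, 1, 2, 3, 5)
  line <- fit_linear_calibration(conc, 158.62 * conc + 2.6371)
  expect_equal(line$slope, 158.62, tolerance = 1e-10)
  expect_equal(line$intercept, 2.6371, tolerance = 1e-10)
  expect_equal(line$r_squared, 1)

  two <- fit_linear_calibration(c(0, 1), c(0, 1))
  expect_equal(two$slope, 1)
  expect_equal(two$intercept, 0, tolerance = 1e-12)

  # OLS sampling theory: slope within 3 standard errors of truth
  withr::with_seed(42, {
    x <- runif(50, 0.5, 5)
    y <- 158.62 * x + 2.6371 + rnorm(50, sd = 5)
  })
  fit <- fit_linear_calibration(x, y)
  se_slope <- 5 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - 158.62), 3 * se_slope)

  expect_error(fit_linear_calibration(c(1, 1, 1), c(1, 2, 3)),
               "distinct concentrations")
})

test_that("trapezoidal peak integration matches geometric and analytic areas", {
  # rectangle of height 3 over width 10
  rect <- chromatogram(seq(0, 10, 0.1), rep(3, 101))
  expect_equal(integrate_peak(rect, 0, 10, "zero"), 30)
  # flat trace under a linear-endpoints baseline integrates to zero
  expect_equal(integrate_peak(rect, 0, 10, "linear"), 0)

  # Gaussian of known analytic area, grid step <= sigma/10
  sd <- 0.5; amp <- 7
  v <- seq(0, 20, by = sd / 10)
  g <- chromatogram(v, amp * exp(-((v - 10)^2) / (2 * sd^2)))
  expect_equal(integrate_peak(g, 0, 20), gaussian_area(amp, sd),
               tolerance = 1e-3)

  expect_error(integrate_peak(rect, -1, 5), "outside")
  expect_error(integrate_peak(rect, 5, 5), "left bound")
})

test_that("calibration inversion clamps below the intercept and is monotone", {
  line <- sec_calibration()
  c0 <- calibration_to_concentration(2.6371, line)
  expect_equal(as.numeric(c0), 0)
  expect_equal(as.numeric(calibration_to_concentration(161.2571, line)), 1.0)
  expect_equal(as.numeric(calibration_to_concentration(795.7371, line)), 5.0)

  below <- calibration_to_concentration(1.0, line)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "below_limit"))

  areas <- seq(0, 1000, length.out = 200)
  conc <- as.numeric(calibration_to_concentration(areas, line))
  expect_true(all(diff(conc) >= 0))
})

test_that("percent dry weight follows the extraction mass balance", {
  expect_equal(percent_dw(1.0, 30, 1.5), 2.0)
  expect_equal(percent_dw(0, 30, 1.5), 0)
  expect_equal(percent_dw(5.0, 30, 1.5), 10.0)
  # linear in volume, inverse in sample mass
  expect_equal(percent_dw(1.0, 60, 1.5), 2 * percent_dw(1.0, 30, 1.5))
  expect_equal(percent_dw(1.0, 30, 3.0), percent_dw(1.0, 30, 1.5) / 2)
  expect_error(percent_dw(1.0, 30, 0), "positive")
})

test_that("per-plant CGP reproduces the event table at one-decimal rounding", {
  expect_equal(cgp_per_plant(38.6, 11.4, digits = 1), 4.4)
  expect_equal(cgp_per_plant(67.8, 7.4, digits = 1), 5.0)
  expect_equal(cgp_per_plant(0, 11.4), 0)
})

test_that("noiseless chromatogram round-trip recovers the input concentration", {
  line <- sec_calibration()
  for (conc in c(0.5, 1.2, 2.5, 5)) {
    ch <- generate_chromatogram(conc, line, noise_sd = 0)
    area <- integrate_peak(ch, ch$volume_mL[1], ch$volume_mL[nrow(ch)])
    back <- as.numeric(calibration_to_concentration(area, line))
    expect_lt(abs(back - conc) / conc, 1e-6)
  }
})

test_that("chromatogram CSV IO round-trips", {
  ch <- generate_chromatogram(1, noise_sd = 0.2, seed = 3, n_points = 101)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, f)
  back <- read_chromatogram(f)
  expect_equal(back$signal_mAu, ch$signal_mAu, tolerance = 1e-12)
})

test_that("quantify_samples produces the standard result columns", {
  chroms <- lapply(c(0.5, 2), generate_chromatogram, noise_sd = 0)
  q <- quantify_samples(chroms)
  expect_named(q, c("sample_id", "area", "concentration_mg_per_ml",
                    "below_limit", "percent_dw"))
  expect_equal(q$concentration_mg_per_ml, c(0.5, 2), tolerance = 1e-6)
  expect_equal(q$percent_dw, c(1, 4), tolerance = 1e-6)
})
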