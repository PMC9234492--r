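test_that("trial generator produces the full randomized-block layout", {
  des <- trial_design()
  expect_equal(des$plants_per_plot, 27L)
  rec <- generate_trial(des, default_event_params(), seed = 1)
  expect_equal(nrow(rec), 4 * 7 * 27)
  # invariants
  expect_true(all(rec$biomass_dw <= rec$biomass_fw))
  expect_true(all(rec$biomass_dw >= 0 & rec$seed_yield >= 0))
  zero_geno <- rec$genotype %in% c("null", "control")
  expect_true(all(rec$cgp_fraction[zero_geno] == 0))
  expect_true(all(rec$cgp_fraction[!zero_geno] > 0))
  expect_true(all(rec$cgp_fraction[rec$event_id == "NIC"] == 0))
  # determinism
  expect_identical(rec, generate_trial(des, default_event_params(), seed = 1))
  expect_false(identical(rec,
                         generate_trial(des, default_event_params(),
                                        seed = 2)))
  expect_error(trial_design(n_blocks = 0), "integer >= 1")
  expect_error(generate_trial(des, default_event_params()[1:3, ]),
               "one parameter row per")
})

test_that("selfed offspring segregate 1:2:1 and carriers match the event mean", {
  # one event, >= 10,000 plants
  des <- trial_design(n_blocks = 40, events = "531", rows_per_plot = 10,
                      plants_per_row = 25, control = NA)
  p <- default_event_params()
  rec <- generate_trial(des, p[p$event_id == "531", ], seed = 3)
  n <- nrow(rec)
  expect_equal(n, 10000)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(rec$genotype == "null") - 0.25), 3 * se)
  # mean per-plant CGP of carriers ~ 38.6 g x 11.4% = 4.4 g
  carriers <- rec[rec$genotype != "null", ]
  cgp <- cgp_per_plant(carriers$biomass_dw, carriers$cgp_fraction)
  expect_equal(mean(cgp), 4.4, tolerance = 0.02)
})

test_that("synthetic chromatograms satisfy the calibration-area identity", {
  line <- sec_calibration()
  # zero concentration still shows the intercept area
  ch0 <- generate_chromatogram(0, line, noise_sd = 0)
  expect_equal(integrate_peak(ch0, 0, 25), 2.6371, tolerance = 1e-9)
  ch1 <- generate_chromatogram(1.0, line, noise_sd = 0)
  expect_equal(integrate_peak(ch1, 0, 25), 161.2571, tolerance = 1e-9)
  expect_true(all(diff(ch1$volume_mL) > 0))
  # seeding contract for noisy traces
  a <- generate_chromatogram(1, line, noise_sd = 1, seed = 1)
  b <- generate_chromatogram(1, line, noise_sd = 1, seed = 2)
  c2 <- generate_chromatogram(1, line, noise_sd = 1, seed = 1)
  expect_false(identical(a$signal_mAu, b$signal_mAu))
  expect_identical(a$signal_mAu, c2$signal_mAu)
  expect_error(generate_chromatogram(-1), "non-negative")
})

test_that("extraction batches scale by the material efficiency", {
  expect_equal(generate_extraction_batches(4.0, "lyophilized", 3, seed = 1),
               rep(4.0, 3))
  expect_equal(generate_extraction_batches(4.0, "silage", 2, seed = 1,
                                           rel_sd = 0), rep(3.88, 2))
  x <- generate_extraction_batches(4.0, "dried_leaf", 10000, seed = 2)
  ratio <- x / 4.0
  expect_lt(abs(mean(ratio) - 0.55), 3 * sd(ratio) / sqrt(10000))
  expect_error(generate_extraction_batches(4.0, "fresh"), "arg")
})

test_that("choice generator matches closed-form logit shares", {
  des <- build_design(seed = 10)
  p <- ncol(des$X)
  # flat utilities: every option an equal 1/5 share
  cd0 <- generate_choice_data(des, rep(0, p), 0, 400, seed = 11)
  shares <- tapply(cd0$chosen, cd0$alt, mean)
  expect_true(all(abs(unname(shares) - 0.2) <
                  3 * sqrt(0.2 * 0.8 / (400 * 12))))
  # dominance: a huge part-worth wins whenever available
  mu <- setNames(rep(0, p), colnames(des$X))
  mu["material.GM_bioplastic"] <- 50
  cdd <- generate_choice_data(des, mu, 0, 20, seed = 12)
  has_gm <- unique(des$profiles$task[des$profiles$material == "GM_bioplastic"])
  idx <- which(cdd$chosen & cdd$task %in% has_gm)
  mat <- des$profiles$material[match(paste(cdd$task[idx], cdd$alt[idx]),
                                     paste(des$profiles$task,
                                           des$profiles$alt))]
  expect_true(all(mat == "GM_bioplastic"))
  # moderate GM preference: empirical shares within 3 multinomial SE
  mu["material.GM_bioplastic"] <- 0.8
  cdm <- generate_choice_data(des, mu, 0, 500, seed = 13)
  expected <- logit_share_oracle(des, mu)
  emp <- tapply(cdm$chosen, cdm$alt, mean)
  se <- sqrt(expected * (1 - expected) / (500 * 12))
  expect_true(all(abs(unname(emp) - expected) < 3 * se + 1e-3))
  # dimension mismatch
  expect_error(generate_choice_data(des, rep(0, p - 1), 0, 5, seed = 1),
               "length")
})

test_that("trial CSV writer emits a readable header row", {
  rec <- generate_trial(trial_design(), default_event_params(), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(names(back), names(rec))
})
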