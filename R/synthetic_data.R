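#' Randomized-block field-trial design
#'
#' Layout of the CGP tobacco trial: events (transgenic lines plus a
#' near-isogenic control) replicated over complete blocks, each plot holding
#' `rows_per_plot * plants_per_row` plants. The default mirrors the field
#' season: 4 blocks, 6 transgenic events + NIC, 3 rows of 9 plants per
#' 12 m^2 plot, 22,000 plants/ha planting density.
#'
#' @param n_blocks number of complete blocks (>= 1).
#' @param events character vector of event labels; the control must be
#'   named in `control`.
#' @param rows_per_plot,plants_per_row plot geometry.
#' @param planting_density plants per hectare (> 0).
#' @param control label of the non-transgenic control event.
#' @return an object of class `trial_design` with derived
#'   `plants_per_plot`.
#' @export
#' @examples
#' trial_design()
trial_design <- function(n_blocks = 4,
                         events = c("531", "549", "521", "507", "536", "532",
                                    "NIC"),
                         rows_per_plot = 3, plants_per_row = 9,
                         planting_density = 22000, control = "NIC") {
  stop_if_not_count(n_blocks, "n_blocks")
  stop_if_not_count(rows_per_plot, "rows_per_plot")
  stop_if_not_count(plants_per_row, "plants_per_row")
  if (!is.numeric(planting_density) || planting_density <= 0)
    stop("planting density must be positive", call. = FALSE)
  if (length(events) < 1 || anyDuplicated(events))
    stop("events must be a non-empty set of unique labels", call. = FALSE)
  if (!control %in% events && !is.na(control))
    stop("control label not among the events", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 events = as.character(events),
                 rows_per_plot = as.integer(rows_per_plot),
                 plants_per_row = as.integer(plants_per_row),
                 plants_per_plot = as.integer(rows_per_plot * plants_per_row),
                 planting_density = planting_density,
                 control = control),
            class = "trial_design")
}

#' Event-level generating parameters
#'
#' Per-event distributions for the synthetic trial, anchored to the selected
#' T0 events: mean leaf dry biomass and seed yield (g/plant) with their
#' standard deviations, mean CGP content (% dw) for transgene carriers with
#' a lognormal coefficient of variation, the number of integration loci
#' (0 = control), and a multiplicative yield-penalty factor applied to
#' carrier biomass.
#'
#' @param event_id label.
#' @param cgp_fraction_mean mean CGP content of carriers, % dw, in
#'   `[0, 100]`.
#' @param cgp_fraction_cv lognormal CV of the carrier CGP content.
#' @param biomass_dw_mean,biomass_dw_sd dry biomass distribution, g/plant.
#' @param seed_yield_mean,seed_yield_sd seed yield distribution, g/plant.
#' @param locus_count transgene integration loci (0 for the control).
#' @param yield_penalty multiplicative biomass factor for carriers, in
#'   (0, 1].
#' @return one-row data frame of class `event_params`.
#' @export
event_params <- function(event_id, cgp_fraction_mean, cgp_fraction_cv = 0.3,
                         biomass_dw_mean, biomass_dw_sd,
                         seed_yield_mean, seed_yield_sd,
                         locus_count = 1L, yield_penalty = 1) {
  stopifnot(cgp_fraction_mean >= 0, cgp_fraction_mean <= 100,
            cgp_fraction_cv >= 0, biomass_dw_sd >= 0, seed_yield_sd >= 0,
            locus_count >= 0, yield_penalty > 0, yield_penalty <= 1)
  structure(data.frame(event_id = as.character(event_id),
                       cgp_fraction_mean = cgp_fraction_mean,
                       cgp_fraction_cv = cgp_fraction_cv,
                       biomass_dw_mean = biomass_dw_mean,
                       biomass_dw_sd = biomass_dw_sd,
                       seed_yield_mean = seed_yield_mean,
                       seed_yield_sd = seed_yield_sd,
                       locus_count = as.integer(locus_count),
                       yield_penalty = yield_penalty,
                       stringsAsFactors = FALSE),
            class = c("event_params", "data.frame"))
}

#' Default event parameters from the published T0 selection
#'
#' The six selected events with their printed biomass, seed yield and CGP
#' content, plus the NIC (mean 42.3 +- 14.7 g biomass, 8.1 +- 2.7 g seed).
#' Per-event standard deviations are not printed; the NIC coefficients of
#' variation are applied to each event mean. Events 531 and 549 carry more
#' than one integration locus (coded 2), the others one, the NIC zero.
#'
#' Also carries the printed per-plant CGP harvest (`printed_cgp_per_plant`)
#' so the biomass x fraction identity can be checked: see
#' [check_table_consistency()].
#'
#' @return data frame of stacked [event_params()] rows with the extra
#'   column `printed_cgp_per_plant`.
#' @export
default_event_params <- function() {
  tab <- data.frame(
    event_id = c("531", "549", "521", "507", "536", "532", "NIC"),
    biomass_dw_mean = c(38.6, 31.9, 67.8, 41.2, 38.9, 44.1, 42.3),
    seed_yield_mean = c(5.2, 4.9, 7.0, 9.3, 4.3, 10.8, 8.1),
    cgp_fraction_mean = c(11.4, 10.3, 7.4, 5.9, 4.9, 4.6, 0),
    printed_cgp_per_plant = c(4.4, 4.0, 5.0, 2.4, 1.9, 2.0, NA),
    locus_count = c(2L, 2L, 1L, 1L, 1L, 1L, 0L)
  )
  cv_biomass <- 14.7 / 42.3
  cv_seed <- 2.7 / 8.1
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    event_params(tab$event_id[i],
                 cgp_fraction_mean = tab$cgp_fraction_mean[i],
                 biomass_dw_mean = tab$biomass_dw_mean[i],
                 biomass_dw_sd = tab$biomass_dw_mean[i] * cv_biomass,
                 seed_yield_mean = tab$seed_yield_mean[i],
                 seed_yield_sd = tab$seed_yield_mean[i] * cv_seed,
                 locus_count = tab$locus_count[i])
  }))
  out$printed_cgp_per_plant <- tab$printed_cgp_per_plant
  out
}

#' Check printed per-plant CGP against the biomass x fraction identity
#'
#' For each event, recomputes CGP/plant as `biomass_dw_mean *
#' cgp_fraction_mean / 100` rounded to one decimal and compares with the
#' printed value. Event 549 is inconsistent (31.9 g x 10.3% = 3.3 g, printed
#' 4.0 g); all other rows reproduce the print.
#'
#' @param params output of [default_event_params()] (or same columns).
#' @return data frame with `event_id`, `computed`, `printed`, `consistent`.
#' @export
#' @examples
#' subset(check_table_consistency(), !consistent)$event_id  # "549"
check_table_consistency <- function(params = default_event_params()) {
  stopifnot(all(c("event_id", "biomass_dw_mean", "cgp_fraction_mean",
                  "printed_cgp_per_plant") %in% names(params)))
  params <- params[!is.na(params$printed_cgp_per_plant), ]
  computed <- cgp_per_plant(params$biomass_dw_mean, params$cgp_fraction_mean,
                            digits = 1)
  data.frame(event_id = params$event_id,
             computed = computed,
             printed = params$printed_cgp_per_plant,
             consistent = abs(computed - params$printed_cgp_per_plant) < 0.05)
}

# truncated normal at zero via inverse-CDF (keeps one uniform per draw)
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

# lognormal with expectation `mean` and coefficient of variation `cv`
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic field-trial plant records
#'
#' Simulates one plant record per position of the randomized-block trial.
#' Transgenic plots hold selfed-hemizygote offspring, so genotypes are drawn
#' from the Mendelian 1:2:1 null : hemizygous : homozygous ratio; null
#' segregants and control plants carry no CGP. Carrier CGP content is
#' lognormal around the event mean; biomass and seed yield are
#' zero-truncated normal; fresh weight is dry weight / 0.094 (the silage
#' dry-matter share). Homozygous carriers draw from the same CGP
#' distribution as hemizygous unless a dose effect is requested.
#'
#' @param design a [trial_design()].
#' @param params data frame of [event_params()] rows, one per design event.
#' @param seed integer seed.
#' @param dose_effect multiplicative factor on the homozygous CGP mean
#'   (default 1: no dose effect).
#' @param dw_fraction dry-weight share of fresh weight (default 0.094).
#' @return data frame of plant records: `event_id`, `block`, `plot`, `row`,
#'   `position`, `genotype`, `biomass_fw`, `biomass_dw`, `cgp_fraction`,
#'   `seed_yield`.
#' @export
#' @examples
#' rec <- generate_trial(trial_design(), default_event_params(), seed = 1)
#' nrow(rec)  # 4 * 7 * 27
generate_trial <- function(design, params, seed = NULL, dose_effect = 1,
                           dw_fraction = 0.094) {
  stopifnot(inherits(design, "trial_design"), is.data.frame(params))
  if (!setequal(params$event_id, design$events))
    stop("need exactly one parameter row per design event", call. = FALSE)
  params <- params[match(design$events, params$event_id), ]
  n_per_plot <- design$plants_per_plot
  with_seed(seed, {
    plots <- expand.grid(block = seq_len(design$n_blocks),
                         event_id = design$events,
                         stringsAsFactors = FALSE)
    plots <- plots[order(plots$block), ]
    plots$plot <- seq_len(nrow(plots))
    recs <- lapply(seq_len(nrow(plots)), function(i) {
      ev <- plots$event_id[i]
      p <- params[params$event_id == ev, ]
      is_control <- p$locus_count == 0
      genotype <- if (is_control) rep("control", n_per_plot)
      else sample(c("null", "hemizygous", "homozygous"), n_per_plot,
                  replace = TRUE, prob = c(0.25, 0.5, 0.25))
      carrier <- genotype %in% c("hemizygous", "homozygous")
      bm_mean <- ifelse(carrier, p$biomass_dw_mean * p$yield_penalty,
                        p$biomass_dw_mean)
      biomass_dw <- vapply(bm_mean, function(m)
        rtruncnorm0(1, m, p$biomass_dw_sd), numeric(1))
      cgp <- numeric(n_per_plot)
      if (any(carrier)) {
        mu <- ifelse(genotype[carrier] == "homozygous",
                     p$cgp_fraction_mean * dose_effect, p$cgp_fraction_mean)
        cgp[carrier] <- vapply(mu, function(m)
          rlnorm_mean_cv(1, m, p$cgp_fraction_cv), numeric(1))
      }
      data.frame(event_id = ev,
                 block = plots$block[i],
                 plot = plots$plot[i],
                 row = rep(seq_len(design$rows_per_plot),
                           each = design$plants_per_row),
                 position = rep(seq_len(design$plants_per_row),
                                design$rows_per_plot),
                 genotype = genotype,
                 biomass_dw = biomass_dw,
                 biomass_fw = biomass_dw / dw_fraction,
                 cgp_fraction = cgp,
                 seed_yield = rtruncnorm0(n_per_plot, p$seed_yield_mean,
                                          p$seed_yield_sd))
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out[, c("event_id", "block", "plot", "row", "position", "genotype",
            "biomass_fw", "biomass_dw", "cgp_fraction", "seed_yield")]
  })
}

#' Generate a germination count for a given locus number
#'
#' Selfed seed of a plant hemizygous at `locus_count` unlinked loci is
#' kanamycin-resistant with probability `1 - 0.25^locus_count` (3:1 for one
#' locus, 15:1 for two); the resistant count is binomial. `locus_count = 0`
#' yields an all-sensitive control count.
#'
#' @param locus_count integration loci (>= 0).
#' @param n_seeds seeds germinated (>= 1).
#' @param seed integer seed.
#' @param event_id optional label.
#' @return a [germination_count()].
#' @export
#' @examples
#' generate_segregation_counts(1, 150, seed = 1)
generate_segregation_counts <- function(locus_count, n_seeds, seed = NULL,
                                        event_id = NA_character_) {
  stop_if_not_count(locus_count, "locus_count", min = 0L)
  stop_if_not_count(n_seeds, "n_seeds")
  p <- 1 - 0.25^locus_count
  r <- if (locus_count == 0) 0L
       else with_seed(seed, stats::rbinom(1, n_seeds, p))
  germination_count(n_seeds, r, event_id)
}

#' Generate a synthetic SEC chromatogram
#'
#' Emulates a size-exclusion trace for a CGP extract: a single Gaussian peak
#' on a flat zero baseline whose noiseless trapezoidal area equals
#' `slope * concentration + intercept` under the given calibration (the
#' Gaussian is rescaled so the area identity holds exactly on the grid),
#' plus optional white detector noise.
#'
#' @param concentration CGP concentration, mg/mL (>= 0).
#' @param calibration a [calibration_line()] (default [sec_calibration()]).
#' @param noise_sd detector noise standard deviation, mAu (>= 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param peak_center,peak_sd peak position and width, mL.
#' @param volume_range run volume, mL.
#' @param n_points grid size.
#' @return a [chromatogram()].
#' @export
#' @examples
#' ch <- generate_chromatogram(1.0, noise_sd = 0)
#' integrate_peak(ch, 0, 25)  # 158.62 + 2.6371
generate_chromatogram <- function(concentration,
                                  calibration = sec_calibration(),
                                  noise_sd = 0, seed = NULL,
                                  peak_center = 12, peak_sd = 0.4,
                                  volume_range = c(0, 25),
                                  n_points = 1001) {
  stopifnot(inherits(calibration, "calibration_line"))
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      concentration < 0)
    stop("concentration must be a single non-negative number", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  v <- seq(volume_range[1], volume_range[2], length.out = n_points)
  target_area <- calibration$slope * concentration + calibration$intercept
  shape <- exp(-((v - peak_center)^2) / (2 * peak_sd^2))
  shape_area <- sum(diff(v) * (utils::head(shape, -1) +
                               utils::tail(shape, -1)) / 2)
  s <- shape * target_area / shape_area
  if (noise_sd > 0)
    s <- s + with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
  chromatogram(v, s)
}

#' Generate replicate extraction measurements
#'
#' Emulates measured CGP yields (% dw) from replicate extractions of a
#' material with known true content: `true_fraction` times the material's
#' extraction efficiency times mean-one lognormal noise. Default
#' efficiencies are 1.00 (lyophilized laboratory reference), 0.55 (dried
#' leaf) and 0.97 (silage) with relative standard deviations 0, 0.09 and
#' 0.13 — the published end-to-end anchors.
#'
#' @param true_fraction true CGP content of the material, % dw (>= 0).
#' @param material `"lyophilized"`, `"dried_leaf"` or `"silage"`.
#' @param n_replicates number of replicate extractions.
#' @param seed integer seed.
#' @param efficiency,rel_sd override the material defaults.
#' @return numeric vector of measured % dw values.
#' @export
#' @examples
#' generate_extraction_batches(4.0, "silage", 2, seed = 1, rel_sd = 0) # 3.88
generate_extraction_batches <- function(true_fraction,
                                        material = c("lyophilized",
                                                     "dried_leaf", "silage"),
                                        n_replicates = 2, seed = NULL,
                                        efficiency = NULL, rel_sd = NULL) {
  material <- match.arg(material)
  if (!is.numeric(true_fraction) || true_fraction < 0)
    stop("true fraction must be non-negative", call. = FALSE)
  stop_if_not_count(n_replicates, "n_replicates")
  eff_default <- c(lyophilized = 1.00, dried_leaf = 0.55, silage = 0.97)
  sd_default <- c(lyophilized = 0, dried_leaf = 0.09, silage = 0.13)
  if (is.null(efficiency)) efficiency <- eff_default[[material]]
  if (is.null(rel_sd)) rel_sd <- sd_default[[material]]
  true_fraction * efficiency *
    with_seed(seed, rlnorm_mean_cv(n_replicates, 1, rel_sd))
}

#' Write plant records to CSV
#'
#' UTF-8, '.' decimal separator, header row.
#'
#' @param records output of [generate_trial()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
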