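#' Linear calibration line
#'
#' Response-area calibration `area = slope * concentration + intercept`,
#' as fitted for SEC quantification of CGP (peak area in mAu*mL against
#' standards of known mg/mL) or, with microgram-scale units, for Bradford
#' quantification on a microplate.
#'
#' @param slope response units per concentration unit; must be positive.
#' @param intercept response units at zero concentration.
#' @param r_squared coefficient of determination, in `[0, 1]` (optional).
#' @return an object of class `calibration_line`.
#' @export
#' @examples
#' sec_calibration()
calibration_line <- function(slope, intercept, r_squared = NA_real_) {
  stopifnot(is.numeric(slope), length(slope) == 1,
            is.numeric(intercept), length(intercept) == 1)
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration: area = %.6g * concentration + %.6g", x$slope,
              x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4g)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Published SEC calibration for CGP
#'
#' The size-exclusion-chromatography calibration determined with CGP
#' standards from 0.5 to 5 mg/mL:
#' peak area (mAu*mL) = 158.62 x concentration (mg/mL) + 2.6371, R^2 = 0.99.
#'
#' @return a [calibration_line()].
#' @export
sec_calibration <- function() calibration_line(158.62, 2.6371, 0.99)

#' Fit a linear calibration by ordinary least squares
#'
#' @param concentration standard concentrations (>= 2 distinct values).
#' @param response measured responses (peak areas, absorbances), same length.
#' @return a [calibration_line()] with the fitted slope, intercept and R^2.
#' @export
#' @examples
#' fit_linear_calibration(c(0.5, 1, 2, 5), 158.62 * c(0.5, 1, 2, 5) + 2.6371)
fit_linear_calibration <- function(concentration, response) {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response))
  if (length(unique(concentration)) < 2)
    stop("calibration needs at least two distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(response ~ concentration)
  co <- stats::coef(fit)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  calibration_line(unname(co[2]), unname(co[1]), r2)
}

#' Chromatogram trace
#'
#' A detector trace for peak integration: retention volume (mL, strictly
#' increasing) and detector signal (mAu), same length.
#'
#' @param volume retention volume grid, mL.
#' @param signal detector signal, mAu.
#' @return an object of class `chromatogram` (a data frame with columns
#'   `volume_mL`, `signal_mAu`).
#' @export
chromatogram <- function(volume, signal) {
  stopifnot(is.numeric(volume), is.numeric(signal))
  if (length(volume) != length(signal))
    stop("volume and signal must have the same length", call. = FALSE)
  if (length(volume) < 2 || any(diff(volume) <= 0))
    stop("volume must be strictly increasing with >= 2 points", call. = FALSE)
  structure(data.frame(volume_mL = volume, signal_mAu = signal),
            class = c("chromatogram", "data.frame"))
}

#' Read / write chromatogram CSV
#'
#' Two-column CSV with header `volume_mL,signal_mAu`, '.' decimal separator.
#'
#' @param path file path.
#' @return `read_chromatogram()` returns a [chromatogram()];
#'   `write_chromatogram()` returns `path` invisibly.
#' @export
read_chromatogram <- function(path) {
  d <- utils::read.csv(path)
  chromatogram(d$volume_mL, d$signal_mAu)
}

#' @rdname read_chromatogram
#' @param chrom a [chromatogram()].
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' Trapezoidal peak integration
#'
#' Integrates `signal - baseline` over `[left, right]` by the trapezoid rule,
#' the programmatic counterpart of manual peak integration on the
#' chromatography workstation. `baseline = "zero"` integrates the raw signal;
#' `baseline = "linear"` subtracts the chord through the signal at the two
#' integration bounds. Bounds falling between grid points are handled by
#' linear interpolation of the trace.
#'
#' @param chrom a [chromatogram()].
#' @param left,right integration bounds in mL, inside the trace range.
#' @param baseline `"zero"` or `"linear"`.
#' @return peak area in mAu*mL.
#' @export
#' @examples
#' tr <- chromatogram(0:10, c(0, 0, 0, 1, 2, 3, 2, 1, 0, 0, 0))
#' integrate_peak(tr, 0, 10)
integrate_peak <- function(chrom, left, right,
                           baseline = c("zero", "linear")) {
  stopifnot(inherits(chrom, "chromatogram"))
  baseline <- match.arg(baseline)
  v <- chrom$volume_mL; s <- chrom$signal_mAu
  if (left >= right) stop("left bound must be below right bound", call. = FALSE)
  if (left < v[1] || right > v[length(v)])
    stop("integration bounds outside the recorded volume range", call. = FALSE)
  inside <- v > left & v < right
  vv <- c(left, v[inside], right)
  ss <- c(stats::approx(v, s, left)$y, s[inside], stats::approx(v, s, right)$y)
  if (baseline == "linear") {
    base <- ss[1] + (ss[length(ss)] - ss[1]) * (vv - left) / (right - left)
    ss <- ss - base
  }
  sum(diff(vv) * (utils::head(ss, -1) + utils::tail(ss, -1)) / 2)
}

#' Invert a calibration line
#'
#' Converts a peak area to concentration, `(area - intercept) / slope`.
#' Areas at or below the intercept are below the quantification limit: the
#' returned concentration is clamped to 0 and flagged via the
#' `below_limit` attribute (a logical vector parallel to the input).
#'
#' @param area peak area(s), response units.
#' @param line a [calibration_line()].
#' @return concentration(s) in the calibration's concentration units, with
#'   attribute `below_limit`.
#' @export
#' @examples
#' calibration_to_concentration(161.2571, sec_calibration())  # 1 mg/mL
calibration_to_concentration <- function(area, line) {
  stopifnot(inherits(line, "calibration_line"), is.numeric(area))
  conc <- (area - line$intercept) / line$slope
  below <- conc < 0
  conc[below] <- 0
  structure(conc, below_limit = below)
}

#' CGP content as percent of dry weight
#'
#' Mass balance of one extraction: `concentration` mg/mL in an extract of
#' `extract_volume` mL, from `sample_dw` grams of dry starting material,
#' gives `100 * concentration * extract_volume / (sample_dw * 1000)` % dw.
#' At the standard bench scale (30 mL extract from 1.5 g dw), 1 mg/mL
#' corresponds to 2% dw.
#'
#' @param concentration mg/mL of CGP in the extract.
#' @param extract_volume extract volume, mL.
#' @param sample_dw dry mass of starting material, g (> 0).
#' @return percent of dry weight.
#' @export
#' @examples
#' percent_dw(1.0, 30, 1.5)  # 2
percent_dw <- function(concentration, extract_volume, sample_dw) {
  stopifnot(all(concentration >= 0), all(extract_volume >= 0))
  if (any(sample_dw <= 0)) stop("sample dry mass must be positive",
                                call. = FALSE)
  100 * (concentration * extract_volume) / (sample_dw * 1000)
}

#' CGP harvest per plant
#'
#' Grams of CGP per plant from leaf biomass (g dry weight) and CGP content
#' (% of dry weight): `biomass_dw * fraction / 100`.
#'
#' @param biomass_dw leaf dry biomass, g/plant.
#' @param fraction CGP content, % dw.
#' @param digits if non-`NULL`, round half away from zero to this many
#'   decimals (the event tables print one decimal).
#' @return grams of CGP per plant.
#' @export
#' @examples
#' cgp_per_plant(38.6, 11.4, digits = 1)  # 4.4
cgp_per_plant <- function(biomass_dw, fraction, digits = NULL) {
  stopifnot(all(biomass_dw >= 0), all(fraction >= 0))
  g <- biomass_dw * fraction / 100
  if (!is.null(digits)) g <- round_half_up(g, digits)
  g
}

#' Quantify chromatograms end to end
#'
#' Integrates each trace, inverts the calibration and converts to % dw.
#'
#' @param chroms list of [chromatogram()] objects.
#' @param line a [calibration_line()].
#' @param extract_volume extract volume per sample, mL.
#' @param sample_dw dry mass per sample, g.
#' @param sample_id optional identifiers.
#' @param baseline passed to [integrate_peak()].
#' @return data frame with columns `sample_id`, `area`,
#'   `concentration_mg_per_ml`, `below_limit`, `percent_dw`.
#' @export
quantify_samples <- function(chroms, line = sec_calibration(),
                             extract_volume = 30, sample_dw = 1.5,
                             sample_id = NULL, baseline = "zero") {
  stopifnot(is.list(chroms))
  if (is.null(sample_id)) sample_id <- seq_along(chroms)
  area <- vapply(chroms, function(ch) {
    integrate_peak(ch, ch$volume_mL[1], ch$volume_mL[nrow(ch)],
                   baseline = baseline)
  }, numeric(1))
  conc <- calibration_to_concentration(area, line)
  data.frame(sample_id = sample_id,
             area = area,
             concentration_mg_per_ml = as.numeric(conc),
             below_limit = attr(conc, "below_limit"),
             percent_dw = percent_dw(as.numeric(conc), extract_volume,
                                     sample_dw))
}
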