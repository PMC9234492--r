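#' Germination count record
#'
#' Kanamycin-resistance counts from a germination assay of selfed seed:
#' `n_resistant` resistant seedlings out of `n_seeds` germinated.
#'
#' @param n_seeds total seeds scored (>= 1).
#' @param n_resistant resistant seedlings, `0 <= n_resistant <= n_seeds`.
#' @param event_id optional event label.
#' @return an object of class `germination_count`.
#' @export
germination_count <- function(n_seeds, n_resistant, event_id = NA_character_) {
  stop_if_not_count(n_seeds, "n_seeds")
  stop_if_not_count(n_resistant, "n_resistant", min = 0L)
  if (n_resistant > n_seeds)
    stop("resistant count exceeds total seeds", call. = FALSE)
  structure(list(event_id = event_id, n_seeds = as.integer(n_seeds),
                 n_resistant = as.integer(n_resistant)),
            class = "germination_count")
}

#' Chi-square goodness of fit for a segregation ratio
#'
#' Tests observed resistant/sensitive counts against an expected resistant
#' proportion (3:1 for one locus, 15:1 for two unlinked loci) with a 1-df
#' chi-square on the two cells.
#'
#' @param counts a [germination_count()].
#' @param ratio expected resistant proportion, in (0, 1). Default 0.75.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic` and `p_value`.
#' @export
#' @examples
#' ratio_goodness_of_fit(germination_count(150, 113), 0.75)
ratio_goodness_of_fit <- function(counts, ratio = 0.75, correct = FALSE) {
  stopifnot(inherits(counts, "germination_count"))
  if (ratio <= 0 || ratio >= 1)
    stop("expected ratio must be strictly inside (0, 1)", call. = FALSE)
  obs <- c(counts$n_resistant, counts$n_seeds - counts$n_resistant)
  exp <- counts$n_seeds * c(ratio, 1 - ratio)
  if (any(exp == 0)) stop("expected count of zero", call. = FALSE)
  dev <- abs(obs - exp)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / exp)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Classify transgene integration loci from segregation counts
#'
#' Implements the field rule for selfed hemizygote seed: ~75% resistant
#' seedlings indicate a single integration locus, any value above 80%
#' indicates multiple integrations. The 75% anchor is operationalized as a
#' window: `single_locus` iff the resistant fraction is <= 0.80 *and* a
#' chi-square goodness-of-fit against 3:1 is not rejected (p > `alpha`);
#' a fraction of exactly 0 is `non_transgenic`; everything else (low
#' fractions incompatible with 3:1) is `inconclusive`.
#'
#' @param counts a [germination_count()].
#' @param alpha significance level for the 3:1 goodness-of-fit gate.
#' @param correct Yates correction for the gate test.
#' @return list of class `locus_classification`: `label` (one of
#'   `single_locus`, `multiple_loci`, `inconclusive`, `non_transgenic`),
#'   `resistant_fraction`, `gof_p`.
#' @export
#' @examples
#' classify_loci(germination_count(150, 113))$label  # single_locus
#' classify_loci(germination_count(150, 128))$label  # multiple_loci
classify_loci <- function(counts, alpha = 0.05, correct = FALSE) {
  stopifnot(inherits(counts, "germination_count"))
  frac <- counts$n_resistant / counts$n_seeds
  gof <- ratio_goodness_of_fit(counts, 0.75, correct = correct)
  label <- if (frac == 0) "non_transgenic"
  else if (frac > 0.80) "multiple_loci"
  else if (gof$p_value > alpha) "single_locus"
  else "inconclusive"
  structure(list(label = label, resistant_fraction = frac,
                 gof_p = gof$p_value),
            class = "locus_classification")
}

#' @export
print.locus_classification <- function(x, ...) {
  cat(sprintf("%s (resistant fraction %.3f, 3:1 GOF p = %.3g)\n",
              x$label, x$resistant_fraction, x$gof_p))
  invisible(x)
}

#' Assess homozygosity from T2 germination counts
#'
#' A T1 plant is called `homozygous` when none of its T2 seedlings are
#' kanamycin-sensitive and the sample is large enough to rule out 3:1
#' segregation by chance (`n_seeds >= min_n`; below that, an all-resistant
#' plate is `inconclusive` — 10/10 resistant happens with probability
#' ~0.056 under 3:1). A count compatible with 3:1 (goodness-of-fit
#' p > `alpha`) is `segregating`; anything else is `inconclusive`.
#'
#' @param counts a [germination_count()] from T2 seed.
#' @param alpha significance level for the 3:1 compatibility test.
#' @param min_n minimum seeds for an all-resistant homozygous call.
#' @return one of `"homozygous"`, `"segregating"`, `"inconclusive"`.
#' @export
#' @examples
#' assess_homozygosity(germination_count(150, 150))  # homozygous
#' assess_homozygosity(germination_count(150, 114))  # segregating
assess_homozygosity <- function(counts, alpha = 0.05, min_n = 30) {
  stopifnot(inherits(counts, "germination_count"))
  all_resistant <- counts$n_resistant == counts$n_seeds
  if (all_resistant && counts$n_seeds >= min_n) return("homozygous")
  if (all_resistant) return("inconclusive")
  gof <- ratio_goodness_of_fit(counts, 0.75)
  if (gof$p_value > alpha) "segregating" else "inconclusive"
}

#' Classify a table of germination counts
#'
#' Vectorized [classify_loci()] over a data frame read from CSV with columns
#' `event_id`, `n_seeds`, `n_resistant`.
#'
#' @param df data frame with the three columns above.
#' @inheritParams classify_loci
#' @return the input with `resistant_fraction`, `gof_p` and `label` appended.
#' @export
classify_events <- function(df, alpha = 0.05, correct = FALSE) {
  stopifnot(all(c("event_id", "n_seeds", "n_resistant") %in% names(df)))
  res <- lapply(seq_len(nrow(df)), function(i) {
    classify_loci(germination_count(df$n_seeds[i], df$n_resistant[i],
                                    df$event_id[i]),
                  alpha = alpha, correct = correct)
  })
  df$resistant_fraction <- vapply(res, `[[`, numeric(1), "resistant_fraction")
  df$gof_p <- vapply(res, `[[`, numeric(1), "gof_p")
  df$label <- vapply(res, `[[`, character(1), "label")
  df
}
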