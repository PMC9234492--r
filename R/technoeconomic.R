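#' Triangular distribution
#'
#' A triangular distribution parameterized by minimum, maximum and mode — the
#' uncertainty model used for extraction yield, purification yield and CGP
#' price in the farm-level revenue simulation. The degenerate case
#' `min == mode == max` is allowed and represents a known constant.
#'
#' @param min lower bound `a`.
#' @param max upper bound `b`.
#' @param mode most-likely value `c`, with `a <= c <= b`.
#' @return an object of class `triangular_dist`.
#' @seealso [sample_triangular()], [scenario_inputs()]
#' @export
#' @examples
#' triangular_dist(0.55, 0.97, 0.90)
triangular_dist <- function(min, max, mode) {
  stopifnot(is.numeric(min), is.numeric(max), is.numeric(mode),
            length(min) == 1, length(max) == 1, length(mode) == 1)
  if (!(min <= mode && mode <= max))
    stop("triangular distribution requires min <= mode <= max", call. = FALSE)
  structure(list(min = min, max = max, mode = mode), class = "triangular_dist")
}

#' @export
print.triangular_dist <- function(x, ...) {
  cat(sprintf("Triangular(min = %g, mode = %g, max = %g)\n",
              x$min, x$mode, x$max))
  invisible(x)
}

#' Triangular distribution function
#'
#' Closed-form CDF of a [triangular_dist()], used both for inverse-CDF sampling
#' and as the reference in Kolmogorov-Smirnov checks of the sampler.
#'
#' @param q numeric quantiles.
#' @param dist a [triangular_dist()].
#' @return vector of probabilities.
#' @export
ptriangular <- function(q, dist) {
  stopifnot(inherits(dist, "triangular_dist"))
  a <- dist$min; b <- dist$max; c <- dist$mode
  if (a == b) return(as.numeric(q >= a))
  p <- numeric(length(q))
  lo <- q <= a; hi <- q >= b
  left <- !lo & !hi & q <= c
  right <- !lo & !hi & q > c
  p[hi] <- 1
  if (c > a) p[left] <- (q[left] - a)^2 / ((b - a) * (c - a))
  if (c < b) p[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - c))
  p
}

#' Triangular quantile function
#'
#' @param p probabilities in `[0, 1]`.
#' @inheritParams ptriangular
#' @return vector of quantiles.
#' @export
qtriangular <- function(p, dist) {
  stopifnot(inherits(dist, "triangular_dist"), all(p >= 0 & p <= 1))
  a <- dist$min; b <- dist$max; c <- dist$mode
  if (a == b) return(rep(a, length(p)))
  fc <- (c - a) / (b - a)
  ifelse(p < fc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF sampling from a single uniform stream, reproducible by seed.
#'
#' @param dist a [triangular_dist()].
#' @param n number of draws.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return numeric vector of `n` draws, all within `[min, max]`.
#' @export
#' @examples
#' x <- sample_triangular(triangular_dist(0, 1, 0.5), 1000, seed = 1)
#' range(x)
sample_triangular <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "triangular_dist"))
  stop_if_not_count(n, "n")
  u <- with_seed(seed, stats::runif(n))
  qtriangular(u, dist)
}

# analytic moments, used as independent cross-checks in tests
triangular_mean <- function(dist) (dist$min + dist$max + dist$mode) / 3

#' Economic scenario inputs
#'
#' The per-hectare production/revenue model inputs: planting density `D`
#' (plants/ha), per-plant CGP harvest `C` (g/plant) and triangular
#' distributions for extraction yield `EY`, purification yield `PY`
#' (both dimensionless fractions) and crude CGP price `P` (USD/kg). Defaults
#' are the published field-trial scenario: 22,000 plants/ha, 4.0 g
#' CGP/plant (the best-performing event), EY from the dried-leaf and silage
#' extraction experiments, and the price band of microbial CGP production
#' cost estimates.
#'
#' @param D planting density, plants per hectare.
#' @param C CGP harvest, grams per plant.
#' @param EY extraction yield distribution, a [triangular_dist()] on `[0, 1]`.
#' @param PY purification yield distribution, a [triangular_dist()] on `[0, 1]`.
#' @param P CGP price distribution, USD per kg.
#' @return an object of class `scenario_inputs`.
#' @export
#' @examples
#' scenario_inputs()
scenario_inputs <- function(D = 22000,
                            C = 4.0,
                            EY = triangular_dist(0.55, 0.97, 0.90),
                            PY = triangular_dist(0.70, 0.93, 0.90),
                            P = triangular_dist(275, 550, 330)) {
  stopifnot(is.numeric(D), length(D) == 1, D > 0,
            is.numeric(C), length(C) == 1, C >= 0,
            inherits(EY, "triangular_dist"), inherits(PY, "triangular_dist"),
            inherits(P, "triangular_dist"))
  if (EY$min < 0 || EY$max > 1 || PY$min < 0 || PY$max > 1)
    stop("EY and PY must be supported in [0, 1]", call. = FALSE)
  structure(list(D = D, C = C, EY = EY, PY = PY, P = P),
            class = "scenario_inputs")
}

#' Deterministic scenario table
#'
#' Bound/mode arithmetic of the per-hectare model:
#' `PR = D * C / 1000` kg/ha of CGP produced, total yield factor
#' `Y = EY * PY` componentwise over (min, max, mode), extracted CGP
#' `E = PR * Y`, and revenue `R = E * P` — with `R` computed from the
#' *unrounded* `E` (the display rounds `E` to whole kg, but
#' 33.88 kg/ha x 275 USD/kg = 9,317 USD/ha, not 34 x 275 = 9,350).
#'
#' @param inputs a [scenario_inputs()].
#' @return an object of class `scenario_table` with unrounded components
#'   `PR`, `Y`, `E`, `R` (each of the last three a named (min, max, mode)
#'   vector) and a `display` data frame with the table-style rounding
#'   (`Y` to 2 decimals, `E` and `R` to whole units, half away from zero).
#' @export
#' @examples
#' scenario_table(scenario_inputs())
scenario_table <- function(inputs) {
  stopifnot(inherits(inputs, "scenario_inputs"))
  tri_vec <- function(d) c(min = d$min, max = d$max, mode = d$mode)
  PR <- inputs$D * inputs$C / 1000          # g/ha -> kg/ha
  Y <- tri_vec(inputs$EY) * tri_vec(inputs$PY)
  E <- PR * Y
  R <- E * tri_vec(inputs$P)
  display <- data.frame(
    quantity = c("PR [kg/ha]", "Y", "E [kg/ha]", "R [USD/ha]"),
    min  = c(PR, round_half_up(Y[1], 2), round_half_up(E[1]), round_half_up(R[1])),
    max  = c(PR, round_half_up(Y[2], 2), round_half_up(E[2]), round_half_up(R[2])),
    mode = c(PR, round_half_up(Y[3], 2), round_half_up(E[3]), round_half_up(R[3])),
    stringsAsFactors = FALSE
  )
  structure(list(inputs = inputs, PR = PR, Y = Y, E = E, R = R,
                 display = display),
            class = "scenario_table")
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("Per-hectare CGP production scenario (min / max / mode)\n")
  cat(sprintf("  D = %s plants/ha, C = %g g/plant\n",
              format(x$inputs$D, big.mark = ","), x$inputs$C))
  d <- x$display
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-11s %s  %s  %s\n", d$quantity[i],
                format(d$min[i], big.mark = ","),
                format(d$max[i], big.mark = ","),
                format(d$mode[i], big.mark = ",")))
  invisible(x)
}

#' Six-number summary
#'
#' Minimum, first quartile, median, mean, third quartile and maximum — the
#' summary layout used to report the Monte Carlo yield and revenue
#' distributions. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param x numeric vector with at least one value.
#' @return named numeric vector `(min, q1, median, mean, q3, max)`.
#' @export
#' @examples
#' summarize_samples(1:5)
summarize_samples <- function(x) {
  if (length(x) < 1 || !is.numeric(x)) stop("need at least one numeric sample",
                                            call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(min = min(x), q1 = q[1], median = q[2], mean = mean(x), q3 = q[3],
    max = max(x))
}

#' Monte Carlo simulation of extracted CGP and revenue
#'
#' Draws extraction yield, purification yield and price independently from
#' their triangular distributions for each repetition, forms
#' `E = PR * EY * PY` (kg/ha) and `R = E * P` (USD/ha), and summarizes both.
#'
#' @param inputs a [scenario_inputs()].
#' @param n_reps number of repetitions (default 100,000).
#' @param seed integer seed for the uniform stream.
#' @param keep_samples keep the per-repetition `E` and `R` vectors in the
#'   result (default `TRUE`; ~1.6 MB at the default size).
#' @return an object of class `mc_result`: `n_reps`, `seed`, six-number
#'   `summary_E` and `summary_R`, and optionally `E`, `R` samples.
#' @export
#' @examples
#' mc <- run_monte_carlo(scenario_inputs(), n_reps = 1000, seed = 7)
#' mc$summary_E
run_monte_carlo <- function(inputs, n_reps = 100000, seed = NULL,
                            keep_samples = TRUE) {
  stopifnot(inherits(inputs, "scenario_inputs"))
  stop_if_not_count(n_reps, "n_reps")
  PR <- inputs$D * inputs$C / 1000
  draws <- with_seed(seed, {
    list(EY = qtriangular(stats::runif(n_reps), inputs$EY),
         PY = qtriangular(stats::runif(n_reps), inputs$PY),
         P  = qtriangular(stats::runif(n_reps), inputs$P))
  })
  E <- PR * draws$EY * draws$PY
  R <- E * draws$P
  out <- list(n_reps = as.integer(n_reps), seed = seed,
              PR = PR,
              summary_E = summarize_samples(E),
              summary_R = summarize_samples(R))
  if (keep_samples) { out$E <- E; out$R <- R }
  structure(out, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo techno-economic simulation (%s repetitions)\n",
              format(x$n_reps, big.mark = ",")))
  m <- rbind(`CGP extracted [kg/ha]` = x$summary_E,
             `Revenue [USD/ha]` = x$summary_R)
  print(round(m, 1))
  invisible(x)
}

#' Fine-chemical revenue scenario
#'
#' Revenue per hectare when the purified CGP is sold into the fine-chemical
#' (dipeptide) market instead of as crude material: mass times price.
#'
#' @param mass kg of CGP per hectare.
#' @param price USD per kg.
#' @return revenue in USD per hectare.
#' @export
#' @examples
#' fine_chemical_revenue(60, 3300)  # 198,000
fine_chemical_revenue <- function(mass, price) {
  stopifnot(all(mass >= 0), all(price >= 0))
  mass * price
}
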