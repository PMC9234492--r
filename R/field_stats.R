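#' Choose a group-comparison test from data properties
#'
#' The gating logic used for the trial statistics: per-group Shapiro-Wilk
#' normality checks and a Levene homogeneity-of-variance check decide between
#' a parametric test (Student t / one-way ANOVA), its Welch variant, or a
#' rank-based test (Wilcoxon-Mann-Whitney / Kruskal-Wallis).
#'
#' Under the `standard` convention a group is treated as normal when
#' Shapiro-Wilk does *not* reject (p > `alpha`) and variances as homogeneous
#' when Levene does not reject. The `paper_literal` convention inverts both
#' gates, reproducing the printed wording of the source protocol
#' ("p <= 0.05 defined as normally distributed" / "defined as homogenous"),
#' which is almost certainly a typo but is kept reproducible.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 3 values each.
#' @param alpha significance level for the gates (default 0.05).
#' @param convention `"standard"` or `"paper_literal"`.
#' @return an object of class `test_plan`: `normality_p` (per group),
#'   `homogeneity_p`, `chosen_test` (one of `"t_test"`, `"anova"`,
#'   `"welch_t"`, `"welch_anova"`, `"wilcoxon"`, `"kruskal"`), `alpha`,
#'   `convention`.
#' @export
#' @examples
#' g <- list(a = rnorm(30), b = rnorm(30, 1))
#' select_test(g)$chosen_test
select_test <- function(groups, alpha = 0.05,
                        convention = c("standard", "paper_literal")) {
  convention <- match.arg(convention)
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("every group needs at least 3 observations", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)

  norm_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(0)  # constant: degenerate, not normal
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  hom_p <- if (stats::sd(values) == 0) 1 else
    car::leveneTest(values ~ labels, center = mean)[1, "Pr(>F)"]

  normal <- if (convention == "standard") all(norm_p > alpha)
            else all(norm_p <= alpha)
  homogeneous <- if (convention == "standard") hom_p > alpha
                 else hom_p <= alpha
  two <- length(groups) == 2
  chosen <- if (normal && homogeneous) { if (two) "t_test" else "anova" }
  else if (normal) { if (two) "welch_t" else "welch_anova" }
  else { if (two) "wilcoxon" else "kruskal" }

  structure(list(normality_p = norm_p, homogeneity_p = hom_p,
                 chosen_test = chosen, alpha = alpha,
                 convention = convention, n_groups = length(groups)),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat(sprintf("Test plan (%s convention): %s\n", x$convention, x$chosen_test))
  cat("  Shapiro-Wilk p:", paste(signif(x$normality_p, 3), collapse = ", "),
      "\n  Levene p:", signif(x$homogeneity_p, 3), "\n")
  invisible(x)
}

#' Run the planned group comparison
#'
#' Executes the test chosen by [select_test()] on the same groups; all tests
#' are two-sided, and significance is declared at `p <= alpha`.
#'
#' @param groups the same list of numeric vectors passed to [select_test()].
#' @param plan a `test_plan`.
#' @return an object of class `test_result`: `test`, `statistic`, `p_value`,
#'   `significant`, `alpha`.
#' @export
#' @examples
#' g <- list(rnorm(30), rnorm(30, 5))
#' compare_groups(g, select_test(g))
compare_groups <- function(groups, plan) {
  stopifnot(inherits(plan, "test_plan"))
  if (length(groups) != plan$n_groups)
    stop("plan was built for a different number of groups", call. = FALSE)
  two <- length(groups) == 2
  if (two != plan$chosen_test %in% c("t_test", "welch_t", "wilcoxon"))
    stop("plan/test mismatch for this number of groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- switch(plan$chosen_test,
    t_test = stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE),
    welch_t = stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE),
    wilcoxon = suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)),
    anova = stats::oneway.test(values ~ labels, var.equal = TRUE),
    welch_anova = stats::oneway.test(values ~ labels, var.equal = FALSE),
    kruskal = stats::kruskal.test(values, labels)
  )
  p <- res$p.value
  structure(list(test = plan$chosen_test,
                 statistic = unname(res$statistic),
                 p_value = p,
                 significant = p <= plan$alpha,
                 alpha = plan$alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Pairwise significance matrix
#'
#' Runs the plan's test family on every pair of groups and returns the
#' logical matrix of significant differences that feeds
#' [letter_display()]. P-values are unadjusted by default; `adjust = "holm"`
#' applies the Holm step-down correction.
#'
#' @param groups list of numeric vectors.
#' @param plan a `test_plan` from [select_test()] on the same groups.
#' @param adjust `"none"` or `"holm"`.
#' @return symmetric logical matrix with `FALSE` diagonal.
#' @export
pairwise_significance <- function(groups, plan, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(plan, "test_plan"), length(groups) == plan$n_groups)
  k <- length(groups)
  pair_test <- switch(plan$chosen_test,
    t_test = , anova = function(a, b)
      stats::t.test(a, b, var.equal = TRUE)$p.value,
    welch_t = , welch_anova = function(a, b)
      stats::t.test(a, b, var.equal = FALSE)$p.value,
    function(a, b) suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE)$p.value)
  )
  idx <- utils::combn(k, 2)
  p <- apply(idx, 2, function(ij) pair_test(groups[[ij[1]]], groups[[ij[2]]]))
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  for (j in seq_len(ncol(idx)))
    sig[idx[1, j], idx[2, j]] <- sig[idx[2, j], idx[1, j]] <- p[j] <= plan$alpha
  sig
}

#' Compact letter display
#'
#' Converts a symmetric matrix of pairwise significant-difference flags into
#' letter labels such that two groups share at least one letter exactly when
#' they are *not* significantly different — the "significance classes" used
#' to annotate trial box plots. Uses the insert-and-absorb algorithm: start
#' with one letter covering all groups; for each significant pair, split
#' every letter containing both; then absorb letters whose membership is a
#' subset of another's.
#'
#' @param sig symmetric logical matrix, `FALSE` diagonal;
#'   `sig[i, j]` is `TRUE` when groups i and j differ significantly.
#' @return character vector of letter strings, one per group.
#' @export
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 3] <- m[3, 1] <- TRUE
#' letter_display(m)  # "a" "ab" "b"
letter_display <- function(sig) {
  if (!is.matrix(sig) || nrow(sig) != ncol(sig))
    stop("need a square matrix of significance flags", call. = FALSE)
  mode(sig) <- "logical"
  if (any(sig != t(sig)) || any(diag(sig)))
    stop("significance matrix must be symmetric with a FALSE diagonal",
         call. = FALSE)
  k <- nrow(sig)
  cols <- list(seq_len(k))  # each column: the set of groups sharing a letter
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb: drop any column whose members are a subset of another column's
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_cols[[a]] %in% new_cols[[b]]) &&
          !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- new_cols[keep]
  }
  # stable letter order: by smallest member
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(g) {
    paste0(letters_pool[which(vapply(cols, function(cl) g %in% cl,
                                     logical(1)))], collapse = "")
  }, character(1))
  names(out) <- rownames(sig)
  out
}
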