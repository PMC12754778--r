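#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is used when `n1 + n2 <= 20` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The method actually used is recorded in the result.
#'
#' @param x,y numeric samples (non-empty).
#' @param n_comparisons number of comparisons for Bonferroni adjustment of
#'   the returned p value (default 1 = no adjustment).
#' @return An object of class `RankTestResult`: list with `U`, `p`,
#'   `adjusted_p`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`,
#'   `n_comparisons`.
#' @export
mann_whitney_u <- function(x, y, n_comparisons = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  p <- min(1, unname(wt$p.value))
  structure(list(
    U = unname(wt$statistic),
    p = p,
    adjusted_p = min(1, p * n_comparisons),
    method = if (exact) "exact" else "normal_approx",
    n1 = length(x), n2 = length(y),
    n_comparisons = n_comparisons
  ), class = "RankTestResult")
}

#' @export
print.RankTestResult <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %.1f (n1 = %d, n2 = %d, %s)\n  two-sided p = %.4g",
    x$U, x$n1, x$n2, x$method, x$p))
  if (x$n_comparisons > 1)
    cat(sprintf(", Bonferroni-adjusted (m = %d) p = %.4g",
                x$n_comparisons, x$adjusted_p))
  cat("\n")
  invisible(x)
}

#' Bonferroni correction
#'
#' Each p value is multiplied by the number of comparisons and capped at 1.
#'
#' @param p_values numeric vector of p values in (0, 1].
#' @param m number of comparisons (default `length(p_values)`).
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p values must lie in (0, 1]")
  p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Box-plot summary with 1.5 IQR whiskers
#'
#' Median and quartiles by linear interpolation (type 7); whiskers at the
#' most extreme data points within 1.5 interquartile ranges of the box.
#'
#' @param sample numeric vector, n >= 1.
#' @return named numeric vector `median, q1, q3, whisker_low, whisker_high`.
#' @export
box_summary <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) == 0) stop("empty sample")
  q <- quantile(sample, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(sample[sample >= q[1] - 1.5 * iqr])
  hi <- max(sample[sample <= q[3] + 1.5 * iqr])
  c(median = q[2], q1 = q[1], q3 = q[3], whisker_low = lo, whisker_high = hi)
}
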