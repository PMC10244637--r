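#' Two-sided Fisher exact test on a 2x2 contingency table
#'
#' Probability-mass method: conditioning on the margins, the first cell
#' follows a hypergeometric distribution; the two-sided p-value sums the
#' probabilities of all margin-preserving tables no more likely than the one
#' observed (relative tolerance 1e-7 on the comparison, guarding against
#' floating-point near-ties).
#'
#' @param table a 2x2 matrix (or something coercible) of non-negative
#'   integer counts; rows = groups, columns = outcome (e.g. correct /
#'   incorrect).
#' @return the two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(7, 5, 8, 10), nrow = 2))  # 0.7104
#' @export
fisher_exact <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("table must contain at least one count", call. = FALSE)
  a <- x[1, 1]
  m1 <- sum(x[1, ])          # row 1 total (white balls)
  m2 <- sum(x[2, ])          # row 2 total (black balls)
  cs <- sum(x[, 1])          # column 1 total (draws)
  support <- max(0, cs - m2):min(m1, cs)
  dens <- stats::dhyper(support, m1, m2, cs)
  obs <- stats::dhyper(a, m1, m2, cs)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Wilcoxon rank-sum test, tie-corrected normal approximation
#'
#' Rank-sum statistic W over the pooled sample with midranks for ties;
#' `z = (W - E[W]) / sqrt(Var[W])` with the tie-corrected variance and no
#' continuity correction; two-sided p from the standard normal.
#'
#' @param x,y numeric samples, each with at least 2 observations.
#' @return an object of class `ranksum_result`: list with `z`, `p`, `W`,
#'   `n1`, `n2`.
#' @export
ranksum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  pooled <- c(x, y)
  N <- n1 + n2
  r <- rank(pooled)  # midranks for ties
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  ties <- table(pooled)
  VW <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (VW > 0) (W - EW) / sqrt(VW) else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(z = z, p = p, W = W, n1 = n1, n2 = n2),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("<ranksum_result> W = %g (n1 = %d, n2 = %d), z = %.3f, p = %.4f\n",
              x$W, x$n1, x$n2, x$z, x$p))
  invisible(x)
}

#' Median and interquartile range (midpoint-interpolation quantiles)
#'
#' Empirical quantile at position `h = q n + 0.5` with linear interpolation
#' between the bracketing order statistics (the "type 5" convention), which
#' is the estimator under which the built-in batteries' printed summaries
#' reproduce.
#'
#' @param values numeric vector, at least one value.
#' @return list with `median`, `q1`, `q3` (25th and 75th percentiles).
#' @examples
#' median_iqr(c(1, 2, 3, 4))$median  # 2.5
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  qmid <- function(v, q) {
    v <- sort(v)
    n <- length(v)
    h <- min(max(q * n + 0.5, 1), n)
    lo <- floor(h)
    hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  list(median = qmid(values, 0.5),
       q1 = qmid(values, 0.25),
       q3 = qmid(values, 0.75))
}
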