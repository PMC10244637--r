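#' @title Exact score distributions (Poisson binomial)
#' @description The total score over a battery — the number of items a random
#'   subject from the reference population answers correctly — follows a
#'   Poisson-binomial distribution with per-item success probabilities equal
#'   to the solution rates. Two routes compute its exact PMF: brute-force
#'   enumeration over all 2^n answer combinations (the oracle, feasible up to
#'   a cap) and an iterative convolution (any n).
#' @name score_pmf
NULL

new_score_pmf <- function(probs, n) {
  names(probs) <- 0:n
  structure(list(probs = probs, n = n), class = "score_pmf")
}

#' @export
print.score_pmf <- function(x, ...) {
  cat(sprintf("<score_pmf> n = %d, mode at score %d\n", x$n,
              pmf_mode(x)$score))
  print(round(x$probs, 6))
  invisible(x)
}

#' Coerce a score PMF to a two-column data frame
#' @param x a `score_pmf`.
#' @param ... unused.
#' @return data frame with columns `score`, `probability` (the data behind a
#'   score-distribution bar plot).
#' @export
as.data.frame.score_pmf <- function(x, ...) {
  data.frame(score = 0:x$n, probability = unname(x$probs))
}

#' Score PMF by full enumeration of answer combinations
#'
#' Materializes the occurrence probability of every one of the 2^n answer
#' combinations and aggregates them by total score. Exponential cost; serves
#' as the independent oracle for [score_pmf_dp()].
#'
#' @param battery a [battery].
#' @param cap largest n accepted (default 20; 2^20 outcomes).
#' @return a `score_pmf` object.
#' @export
score_pmf_enumerate <- function(battery, cap = 20L) {
  p <- solution_rates(battery)
  n <- length(p)
  if (n > cap) {
    stop(sprintf(paste0("enumeration over 2^%d combinations exceeds the cap",
                        " (%d items); use score_pmf_dp()"), n, cap),
         call. = FALSE)
  }
  # every subset's probability and score, built by doubling
  prob <- 1
  score <- 0L
  for (pj in p) {
    prob <- c(prob * (1 - pj), prob * pj)
    score <- c(score, score + 1L)
  }
  probs <- vapply(0:n, function(k) sum(prob[score == k]), numeric(1))
  new_score_pmf(probs, n)
}

#' Score PMF by iterative convolution
#'
#' Dynamic-programming route: start from the empty battery's degenerate PMF
#' and convolve in one Bernoulli item at a time,
#' `probs'[k] = probs[k] (1 - p_j) + probs[k-1] p_j`. O(n^2) time, exact to
#' double precision; agrees with [score_pmf_enumerate()] within 1e-12.
#'
#' @param battery a [battery].
#' @return a `score_pmf` object.
#' @export
score_pmf_dp <- function(battery) {
  p <- solution_rates(battery)
  n <- length(p)
  if (n < 1L) stop("battery must contain at least one item", call. = FALSE)
  v <- 1
  for (pj in p) v <- c(v * (1 - pj), 0) + c(0, v * pj)
  new_score_pmf(v, n)
}

#' Mode of a score PMF
#'
#' The most likely total score. Ties are broken toward the smallest score and
#' flagged, so output is deterministic even on exchangeable batteries.
#'
#' @param pmf a `score_pmf`.
#' @param tol absolute tolerance for declaring a tie (default 1e-12).
#' @return list with `score` (integer) and `tied` (logical).
#' @export
pmf_mode <- function(pmf, tol = 1e-12) {
  stopifnot(inherits(pmf, "score_pmf"))
  top <- max(pmf$probs)
  at <- unname(which(pmf$probs >= top - tol))
  list(score = at[1L] - 1L, tied = length(at) > 1L)
}
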