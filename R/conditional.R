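#' @title Conditional placement of an answer profile
#' @description Given a battery and a profile with total score k, every one
#'   of the C(n, k) answer combinations attaining that score has an
#'   occurrence probability under the reference population. The multiset of
#'   those probabilities is the conditional profile distribution; a profile's
#'   standing within it (percentile rank, membership in the top-q most
#'   probable combinations) measures whether its particular pattern of
#'   correct answers is human-typical, over and above the total score.
#' @name conditional
NULL

#' Exact binomial coefficient
#'
#' Pascal's-rule integer arithmetic carried in doubles; exact as long as the
#' result is below 2^53 (amply covers C(30, 12) = 86,493,225).
#'
#' @param n,k non-negative integers.
#' @return the exact count of k-subsets of n items.
#' @export
exact_choose <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 0L || k > n) return(0)
  row <- 1
  if (n >= 1L) for (i in seq_len(n)) row <- c(row, 0) + c(0, row)
  row[k + 1L]
}

#' Occurrence probability of an answer profile
#'
#' The probability that a random subject from the reference population
#' produces exactly this correct/incorrect pattern:
#' the product of `p_j` over correct items and `1 - p_j` over incorrect
#' items. Accumulated as a sum of logs and exponentiated at the boundary, so
#' behavior is uniform down to arbitrarily small probabilities.
#'
#' @param battery a [battery].
#' @param profile an [answer_profile] (or 0/1 vector) of matching length.
#' @param log if `TRUE` return the log probability.
#' @return a probability (or log probability).
#' @examples
#' profile_probability(battery(c("a", "b"), "s", c(0.5, 0.5)), c(1, 0))  # 0.25
#' @export
profile_probability <- function(battery, profile, log = FALSE) {
  profile <- check_profile_battery(battery, profile)
  p <- solution_rates(battery)
  lp <- sum(base::log(ifelse(profile$bits == 1L, p, 1 - p)))
  if (log) lp else exp(lp)
}

new_conditional_dist <- function(k, n, probabilities, method) {
  m <- exact_choose(n, k)
  if (length(probabilities) != m) {
    stop(sprintf("internal error: enumerated %d combinations, expected C(%d,%d) = %.0f",
                 length(probabilities), n, k, m), call. = FALSE)
  }
  structure(list(k = as.integer(k), n = as.integer(n), m = m,
                 probabilities = probabilities, method = method),
            class = "conditional_dist")
}

#' @export
print.conditional_dist <- function(x, ...) {
  cat(sprintf("<conditional_dist> score %d of %d items: %.0f combinations (%s)\n",
              x$k, x$n, x$m, x$method))
  cat(sprintf("  total mass %.6g, range [%.3g, %.3g]\n",
              sum(x$probabilities), min(x$probabilities), max(x$probabilities)))
  invisible(x)
}

#' Enumerate the conditional profile distribution directly
#'
#' Walks all k-subsets of the battery's items in lexicographic order and
#' computes each combination's occurrence probability. Refused above `cap`
#' combinations; use [enumerate_conditional_mitm()] there.
#'
#' @param battery a [battery].
#' @param k the fixed total score, `0 <= k <= n`.
#' @param cap largest combination count enumerated directly (default 1e7).
#' @return a `conditional_dist`.
#' @export
enumerate_conditional <- function(battery, k, cap = 1e7) {
  p <- solution_rates(battery)
  n <- length(p)
  k <- as.integer(k)
  if (k < 0L || k > n) stop("k must be between 0 and n", call. = FALSE)
  m <- exact_choose(n, k)
  if (m > cap) {
    stop(sprintf(paste0("C(%d,%d) = %.0f combinations exceeds the direct cap ",
                        "(%.0f); use enumerate_conditional_mitm()"),
                 n, k, m, cap), call. = FALSE)
  }
  if (k == 0L || k == n) {
    probs <- if (k == 0L) prod(1 - p) else prod(p)
    return(new_conditional_dist(k, n, probs, "direct"))
  }
  cb <- utils::combn(n, k)
  if (all(p > 0 & p < 1)) {
    lp <- base::log(p)
    lq <- base::log1p(-p)
    base_lq <- sum(lq)
    delta <- lp - lq
    probs <- exp(base_lq + colSums(matrix(delta[cb], nrow = k)))
  } else {
    # degenerate rates (0 or 1): zero-probability combinations still count
    probs <- apply(cb, 2L, function(idx) {
      b <- rep(0L, n)
      b[idx] <- 1L
      prod(ifelse(b == 1L, p, 1 - p))
    })
  }
  new_conditional_dist(k, n, probs, "direct")
}

# All 2^n subset products of a rate vector, grouped by subset size:
# returns a list L with L[[k+1]] = probabilities of all k-subsets.
subset_products_by_count <- function(p) {
  L <- list(1)
  for (pj in p) {
    q <- 1 - pj
    K <- length(L)
    out <- vector("list", K + 1L)
    out[[1L]] <- L[[1L]] * q
    if (K > 1L) for (k in 2:K) out[[k]] <- c(L[[k]] * q, L[[k - 1L]] * pj)
    out[[K + 1L]] <- L[[K]] * pj
    L <- out
  }
  L
}

#' Enumerate the conditional profile distribution by meet-in-the-middle
#'
#' Splits the battery into two halves (first `ceiling(n/2)` items, rest),
#' enumerates each half's sub-score probability lists (2^(n/2) each), and
#' pairs every `(k1, k2)` with `k1 + k2 = k` via chunked outer products.
#' Produces the identical multiset of probabilities as direct enumeration
#' while touching only 2^(n/2) sub-products, which makes the ~86.5-million
#' combination pooled analysis tractable in seconds.
#'
#' @param battery a [battery].
#' @param k the fixed total score.
#' @param chunk_size maximum elements per temporary pairing block
#'   (bounds peak memory; default 5e6 doubles = 40 MB per block).
#' @return a `conditional_dist`.
#' @export
enumerate_conditional_mitm <- function(battery, k, chunk_size = 5e6) {
  if (length(chunk_size) != 1L || !is.finite(chunk_size) || chunk_size < 1) {
    stop("chunk_size must be a positive number", call. = FALSE)
  }
  p <- solution_rates(battery)
  n <- length(p)
  k <- as.integer(k)
  if (k < 0L || k > n) stop("k must be between 0 and n", call. = FALSE)
  n1 <- ceiling(n / 2)
  A <- subset_products_by_count(p[seq_len(n1)])
  B <- subset_products_by_count(p[setdiff(seq_len(n), seq_len(n1))])
  m <- exact_choose(n, k)
  out <- numeric(m)
  pos <- 1L
  for (k1 in max(0L, k - (n - n1)):min(n1, k)) {
    a <- A[[k1 + 1L]]
    b <- B[[k - k1 + 1L]]
    rows_per <- max(1L, floor(chunk_size / length(b)))
    start <- 1L
    while (start <= length(a)) {
      end <- min(start + rows_per - 1L, length(a))
      blk <- as.vector(outer(a[start:end], b))
      out[pos:(pos + length(blk) - 1L)] <- blk
      pos <- pos + length(blk)
      start <- end + 1L
    }
  }
  new_conditional_dist(k, n, out, "mitm")
}

#' Percentile rank of a probability within a conditional distribution
#'
#' Strict-less convention: 100 times the fraction of same-score combinations
#' whose occurrence probability is strictly smaller than `p`. Values within
#' relative tolerance `tol` of `p` count as ties, not as smaller, so an
#' exchangeable battery (all combinations equally likely) yields rank 0 for
#' every profile.
#'
#' @param distribution a `conditional_dist`.
#' @param p a probability.
#' @param tol relative equality tolerance (default 1e-9).
#' @return a value in `[0, 100]`.
#' @export
percentile_rank <- function(distribution, p, tol = 1e-9) {
  stopifnot(inherits(distribution, "conditional_dist"))
  100 * sum(distribution$probabilities < p * (1 - tol)) / distribution$m
}

#' Top-fraction probability threshold of a conditional distribution
#'
#' The nearest-rank upper quantile: sorting the m combination probabilities
#' ascending, the value at rank `ceiling((1 - q) m)`. A profile is "in the
#' top q" (among the fraction q of most probable same-score combinations)
#' when its probability is greater than or equal to this threshold
#' (non-strict, so an all-tied distribution places every profile in the top
#' q at any q).
#'
#' @param distribution a `conditional_dist`.
#' @param q fraction in (0, 1) (default 0.05).
#' @return a probability threshold.
#' @export
top_fraction_threshold <- function(distribution, q = 0.05) {
  stopifnot(inherits(distribution, "conditional_dist"))
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  }
  r <- ceiling((1 - q) * distribution$m)
  sort(distribution$probabilities, partial = r)[r]
}

# Nearest-rank order statistics at the given ascending ranks, via one
# partial sort (avoids fully sorting an 86-million element vector).
order_stats_at <- function(values, ranks) {
  s <- sort(values, partial = ranks)
  s[ranks]
}

#' Place an answer profile within its same-score combination distribution
#'
#' End-to-end conditional placement: computes the profile's score k, builds
#' the conditional distribution over all C(n, k) same-score combinations
#' (direct enumeration up to `direct_cap` combinations, meet-in-the-middle
#' beyond), and reports the profile's occurrence probability, its percentile
#' rank, the top-q threshold and whether it clears it.
#'
#' @param battery a [battery].
#' @param profile an [answer_profile] (or 0/1 vector).
#' @param q top-fraction of interest (default 0.05, the "5% most probable
#'   combinations" convention).
#' @param direct_cap combination count above which the meet-in-the-middle
#'   path is auto-selected (default 1e5).
#' @param chunk_size passed to [enumerate_conditional_mitm()].
#' @param n_quantiles number of evenly spaced order statistics retained for
#'   plotting the distribution (default 512).
#' @return an object of class `placement_report`: a list with
#'   `profile_probability`, `percentile_rank`, `top_q_threshold`, `in_top_q`,
#'   `q`, `k`, `n`, `m`, `method`, and `quantiles` (a data frame of
#'   down-sampled sorted probabilities with rank markers at the 5th, 50th and
#'   95th percentiles; `stride` attribute records the down-sampling step).
#' @examples
#' placement(builtin_battery("practice"), builtin_profile("practice"))
#' @export
placement <- function(battery, profile, q = 0.05, direct_cap = 1e5,
                      chunk_size = 5e6, n_quantiles = 512L) {
  profile <- check_profile_battery(battery, profile)
  k <- profile$score
  n <- n_items(battery)
  m <- exact_choose(n, k)
  dist <- if (m <= direct_cap) enumerate_conditional(battery, k)
  else enumerate_conditional_mitm(battery, k, chunk_size = chunk_size)
  pp <- profile_probability(battery, profile)
  pr <- percentile_rank(dist, pp)
  thr_rank <- ceiling((1 - q) * m)
  grid_n <- min(n_quantiles, m)
  grid <- unique(ceiling(seq(1, m, length.out = grid_n)))
  marker_ranks <- pmin(m, pmax(1, ceiling(c(0.05, 0.50, 0.95) * m)))
  all_ranks <- sort(unique(c(grid, marker_ranks, thr_rank)))
  vals <- order_stats_at(dist$probabilities, all_ranks)
  names(vals) <- all_ranks
  quantiles <- data.frame(rank = all_ranks, probability = vals,
                          marker = ifelse(all_ranks %in% marker_ranks,
                                          paste0("p", c(5, 50, 95)[match(all_ranks, marker_ranks)]),
                                          ""),
                          row.names = NULL)
  attr(quantiles, "stride") <- if (grid_n > 1) (m - 1) / (grid_n - 1) else 1
  thr <- unname(vals[as.character(thr_rank)])
  structure(list(
    profile_probability = pp,
    percentile_rank = pr,
    top_q_threshold = thr,
    in_top_q = pp >= thr,
    q = q, k = k, n = n, m = m,
    method = dist$method,
    quantiles = quantiles
  ), class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("<placement_report> score %d/%d (%.0f same-score combinations, %s)\n",
              x$k, x$n, x$m, x$method))
  cat(sprintf("  profile probability %.3g; percentile rank %.1f\n",
              x$profile_probability, x$percentile_rank))
  cat(sprintf("  top-%.0f%% threshold %.3g -> %s\n", 100 * x$q,
              x$top_q_threshold,
              if (x$in_top_q) "within the most probable fraction"
              else "outside the most probable fraction"))
  invisible(x)
}
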