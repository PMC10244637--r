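test_that("exact_choose is exact integer arithmetic", {
  expect_identical(exact_choose(30, 12), 86493225)
  expect_identical(exact_choose(15, 7), 6435)
  expect_identical(exact_choose(5, 0), 1)
  expect_identical(exact_choose(5, 6), 0)
  for (n in 0:20) for (k in c(0L, n %/% 2L, n)) {
    expect_identical(exact_choose(n, k), choose(n, k))
  }
})

test_that("profile probability follows the product formula", {
  expect_equal(profile_probability(battery(c("a", "b"), "s", c(0.5, 0.5)),
                                   c(1, 0)), 0.25)
  # independence: probability of a concatenated profile factorizes
  for (seed in 1:5) {
    b1 <- random_battery(6, seed)
    b2 <- random_battery(5, seed + 50)
    pooled <- battery(c(paste0("x", 1:6), paste0("y", 1:5)), "s",
                      c(solution_rates(b1), solution_rates(b2)))
    bits1 <- random_bits(6, seed)
    bits2 <- random_bits(5, seed + 50)
    expect_equal(profile_probability(pooled, c(bits1, bits2)),
                 profile_probability(b1, bits1) * profile_probability(b2, bits2),
                 tolerance = 1e-14)
  }
  # log-space route stays finite and consistent far below double underflow ranges
  b <- battery(sprintf("i%d", 1:20), "s", rep(1e-4, 20))
  expect_equal(profile_probability(b, rep(1, 20), log = TRUE), 20 * log(1e-4))
})

test_that("direct conditional enumeration satisfies count and conservation", {
  b <- builtin_battery("practice")
  d <- enumerate_conditional(b, 7)
  expect_identical(d$m, 6435)
  expect_length(d$probabilities, 6435)
  expect_equal(sum(d$probabilities), unname(score_pmf_dp(b)$probs[8]),
               tolerance = 1e-10)
  for (seed in 1:8) {
    n <- sample(3:12, 1)
    k <- sample(0:n, 1)
    rb <- random_battery(n, seed + 300)
    dd <- enumerate_conditional(rb, k)
    expect_identical(dd$m, choose(n, k))
    expect_equal(sum(dd$probabilities),
                 unname(score_pmf_dp(rb)$probs[k + 1]), tolerance = 1e-10)
  }
  expect_error(enumerate_conditional(b, 16), "between 0 and n")
  expect_error(enumerate_conditional(builtin_battery("pooled"), 12),
               "enumerate_conditional_mitm")
})

test_that("meet-in-the-middle yields the same multiset as direct enumeration", {
  for (case in list(list(n = 10, k = 4, seed = 1), list(n = 13, k = 7, seed = 2),
                    list(n = 16, k = 8, seed = 3), list(n = 16, k = 1, seed = 4),
                    list(n = 15, k = 15, seed = 5), list(n = 9, k = 0, seed = 6))) {
    b <- random_battery(case$n, case$seed + 400)
    direct <- sort(enumerate_conditional(b, case$k)$probabilities)
    mitm <- sort(enumerate_conditional_mitm(b, case$k)$probabilities)
    expect_identical(length(mitm), length(direct))
    expect_lt(max_abs_diff(mitm, direct), 1e-12)
  }
  # chunking must not change the result
  b <- random_battery(14, 7)
  ref <- sort(enumerate_conditional_mitm(b, 6)$probabilities)
  expect_equal(sort(enumerate_conditional_mitm(b, 6, chunk_size = 17)$probabilities),
               ref)
  expect_error(enumerate_conditional_mitm(b, 6, chunk_size = 0), "chunk_size")
})

test_that("percentile rank uses the strict-less convention with tolerance", {
  b <- random_battery(10, 11)
  d <- enumerate_conditional(b, 4)
  expect_equal(percentile_rank(d, min(d$probabilities) / 2), 0)
  expect_equal(percentile_rank(d, max(d$probabilities) * 2), 100)
  # a member's own value never counts itself as strictly smaller
  v <- sort(d$probabilities)[100]
  expect_equal(percentile_rank(d, v), 100 * sum(d$probabilities < v * (1 - 1e-9)) / d$m)
  # exchangeable battery: all combinations tie, rank 0 for every profile
  eq <- battery(sprintf("i%d", 1:8), "s", rep(0.4, 8))
  deq <- enumerate_conditional(eq, 3)
  expect_equal(percentile_rank(deq, profile_probability(eq, c(1, 1, 1, rep(0, 5)))), 0)
})

test_that("top-fraction threshold is a nearest-rank quantile, monotone in q", {
  b <- random_battery(12, 12)
  d <- enumerate_conditional(b, 5)
  s <- sort(d$probabilities)
  expect_identical(top_fraction_threshold(d, 0.05), s[ceiling(0.95 * d$m)])
  qs <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.9)
  thr <- vapply(qs, top_fraction_threshold, numeric(1), distribution = d)
  expect_true(all(diff(thr) <= 0))
  expect_error(top_fraction_threshold(d, 1.2), "between 0 and 1")
  # all-tied distribution: threshold equals the common value
  eq <- battery(sprintf("i%d", 1:8), "s", rep(0.4, 8))
  deq <- enumerate_conditional(eq, 3)
  expect_equal(top_fraction_threshold(deq, 0.05), 0.4^3 * 0.6^5)
})

test_that("degenerate rates (0/1) keep zero-probability combinations in the count", {
  b <- battery(c("a", "b", "c", "d"), "s", c(0, 0.5, 1, 0.5))
  d <- enumerate_conditional(b, 2)
  expect_identical(d$m, choose(4, 2))
  expect_length(d$probabilities, 6)
  expect_true(any(d$probabilities == 0))
  expect_equal(sum(d$probabilities), unname(score_pmf_dp(b)$probs[3]),
               tolerance = 1e-12)
  mitm <- enumerate_conditional_mitm(b, 2)
  expect_equal(sort(mitm$probabilities), sort(d$probabilities))
})

test_that("placement auto-selects the enumeration path and is self-consistent", {
  b <- builtin_battery("practice")
  pl <- placement(b, builtin_profile("practice"))
  expect_identical(pl$method, "direct")
  expect_identical(pl$in_top_q, pl$profile_probability >= pl$top_q_threshold)
  expect_true(pl$percentile_rank >= 0 && pl$percentile_rank <= 100)
  # forcing the mitm path gives identical numbers
  pl2 <- placement(b, builtin_profile("practice"), direct_cap = 1)
  expect_identical(pl2$method, "mitm")
  expect_equal(pl2$top_q_threshold, pl$top_q_threshold)
  expect_equal(pl2$percentile_rank, pl$percentile_rank)
  # exchangeable battery: every profile ties at the threshold, so in_top_q
  eq <- battery(sprintf("i%d", 1:8), "s", rep(0.4, 8))
  ple <- placement(eq, c(1, 1, 1, rep(0, 5)))
  expect_equal(ple$percentile_rank, 0)
  expect_true(ple$in_top_q)
  # quantile export carries the three percentile markers
  expect_setequal(setdiff(unique(pl$quantiles$marker), ""), c("p5", "p50", "p95"))
})
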