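test_that("rate models validate their parameters", {
  expect_error(rate_model_uniform(0.9, 0.1), "lo < hi")
  expect_error(rate_model_beta(0, 1), "alpha > 0")
  expect_error(rate_model_fixed(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(simulation_config(0, 10), "n_items")
  expect_error(simulation_config(5, 10, rate_model_fixed(rep(0.5, 3))),
               "length must equal")
})

test_that("battery generation is seed-deterministic", {
  cfg <- simulation_config(10, 100, rate_model_uniform(0.1, 0.8), seed = 7L)
  b1 <- generate_battery(cfg)
  b2 <- generate_battery(cfg)
  expect_identical(b1, b2)
  expect_true(all(solution_rates(b1) >= 0.1 & solution_rates(b1) <= 0.8))
  b3 <- generate_battery(simulation_config(10, 100,
                                           rate_model_uniform(0.1, 0.8),
                                           seed = 8L))
  expect_false(identical(solution_rates(b1), solution_rates(b3)))
  fixed <- generate_battery(simulation_config(10, 1,
                                              rate_model_fixed(rep(0.5, 10))))
  expect_identical(solution_rates(fixed), rep(0.5, 10))
})

test_that("beta-model rates have the right mean at large n", {
  cfg <- simulation_config(1000, 1, rate_model_beta(2, 2), seed = 11L)
  rates <- solution_rates(generate_battery(cfg))
  se <- sqrt(0.05 / 1000)  # Beta(2,2): mean 1/2, variance 1/20
  expect_lt(abs(mean(rates) - 0.5), 3 * se)
})

test_that("cohorts are Bernoulli(p_j) with deterministic seeds", {
  b <- builtin_battery("practice")
  m1 <- simulate_cohort(b, 50, seed = 3L)
  m2 <- simulate_cohort(b, 50, seed = 3L)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_identical(dim(m1), c(50L, 15L))

  ones <- simulate_cohort(battery(c("a", "b"), "s", c(1, 1)), 20, seed = 1L)
  expect_true(all(ones == 1L))
  zeros <- simulate_cohort(battery(c("a", "b"), "s", c(0, 0)), 20, seed = 1L)
  expect_true(all(zeros == 0L))
})

test_that("per-item empirical rates recover p_j within 3 standard errors", {
  b <- builtin_battery("practice")
  n <- 100000L
  cohort <- simulate_cohort(b, n, seed = 1L)
  emp <- colMeans(cohort)
  p <- solution_rates(b)
  expect_true(all(abs(emp - p) < 3 * sqrt(p * (1 - p) / n)))
})

test_that("empirical score PMF converges to the analytic PMF", {
  b <- builtin_battery("practice")
  analytic <- score_pmf_dp(b)$probs
  cohort <- simulate_cohort(b, 200000L, seed = 9L)
  emp <- empirical_score_pmf(cohort)
  expect_equal(sum(emp$probs), 1)
  tv <- 0.5 * sum(abs(emp$probs - analytic))
  expect_lt(tv, 0.01)
  # and a larger cohort gets closer than a small one (fixed seeds)
  tv_small <- 0.5 * sum(abs(empirical_score_pmf(
    simulate_cohort(b, 500L, seed = 9L))$probs - analytic))
  expect_lt(tv, tv_small)

  point <- empirical_score_pmf(simulate_cohort(
    battery(sprintf("i%d", 1:5), "s", rep(1, 5)), 10L, seed = 1L))
  expect_identical(unname(point$probs), c(0, 0, 0, 0, 0, 1))
})

test_that("Monte-Carlo profile-probability validation is calibrated", {
  b <- battery(c("a", "b"), "s", c(0.5, 0.5))
  v <- validate_profile_probability(b, c(1, 1), 100000L, seed = 13L)
  expect_equal(v$analytic, 0.25)
  expect_lt(abs(v$z_discrepancy), 4)

  sure <- validate_profile_probability(battery(c("a", "b"), "s", c(1, 1)),
                                       c(1, 1), 100L, seed = 1L)
  expect_equal(sure$empirical, 1)
  never <- validate_profile_probability(battery(c("a", "b"), "s", c(1, 0)),
                                        c(0, 1), 1000L, seed = 1L)
  expect_equal(never$empirical, 0)
  expect_equal(never$analytic, 0)
})

test_that("conditional frequency ordering agrees with analytic p_ki ordering", {
  b <- random_battery(8, 77)
  k <- 4L
  n_sub <- 1e6
  cohort <- simulate_cohort(b, n_sub, seed = 21L)
  scores <- rowSums(cohort)
  sel <- cohort[scores == k, , drop = FALSE]
  ids <- as.vector(sel %*% 2^(0:7))
  counts <- table(factor(ids, levels = 0:255))
  cb <- utils::combn(8, k)
  analytic <- apply(cb, 2, function(idx) {
    bits <- rep(0L, 8)
    bits[idx] <- 1L
    profile_probability(b, bits)
  })
  code <- apply(cb, 2, function(idx) sum(2^(idx - 1)))
  observed <- as.numeric(counts[as.character(code)])
  top <- order(analytic, decreasing = TRUE)[1:35]  # top half by analytic prob
  expect_gt(cor(observed[top], analytic[top], method = "spearman"), 0.9)
})

test_that("cohort CSV and config round out to disk", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- simulation_config(4, 25, rate_model_beta(2, 2), seed = 2L)
  bat <- generate_battery(cfg)
  cohort <- simulate_cohort(bat, cfg$n_subjects, seed = derive_seed(cfg$seed, 2L))
  write_cohort(cohort, path, config = cfg)
  back <- as.matrix(utils::read.csv(path))
  expect_identical(dim(back), dim(cohort))
  expect_true(all(back == unclass(cohort)))
  cfg_lines <- readLines(paste0(path, ".config.yml"))
  expect_true(any(grepl("^seed: 2$", cfg_lines)))
})
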