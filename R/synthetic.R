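#' @title Synthetic batteries and simulated cohorts
#' @description The analytic machinery assumes a cohort of independent
#'   subjects, each answering item j correctly with probability `p_j`,
#'   answers independent across items. This module generates data from
#'   exactly that model — synthetic rate vectors and Bernoulli response
#'   matrices — so every analytic quantity (score PMF, profile probability,
#'   conditional ordering) can be validated by Monte Carlo without external
#'   data. A single root seed drives everything through a documented
#'   derivation rule, keeping runs reproducible end to end.
#' @name synthetic_cohort
NULL

#' Derive a purpose-specific sub-seed from a root seed
#'
#' Deterministic rule by which one root seed drives every source of
#' randomness in a run: the root plus a purpose salt, folded into
#' `[0, 2^31)` with a multiplicative mix so nearby roots do not collide.
#' Convention: salt 1 = battery generation, salt 2 = cohort simulation,
#' salt 3 = validation cohorts.
#'
#' @param seed root integer seed.
#' @param salt small integer identifying the purpose.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) * 69069 + as.double(salt) * 12345) %% 2147483647
  as.integer(s)
}

#' Rate models for synthetic batteries
#'
#' Describe how per-item solution rates are drawn: uniformly on
#' `(lo, hi) within [0, 1]`, from a `Beta(alpha, beta)`, or a fixed list.
#'
#' @param lo,hi uniform bounds, `0 <= lo < hi <= 1`.
#' @param alpha,beta positive Beta shape parameters.
#' @param rates fixed numeric vector of rates in `[0, 1]`.
#' @return a `rate_model` list.
#' @name rate_model
NULL

#' @rdname rate_model
#' @export
rate_model_uniform <- function(lo = 0.1, hi = 0.9) {
  if (!(lo >= 0 && hi <= 1 && lo < hi)) {
    stop("uniform rate model requires 0 <= lo < hi <= 1", call. = FALSE)
  }
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "rate_model")
}

#' @rdname rate_model
#' @export
rate_model_beta <- function(alpha = 2, beta = 2) {
  if (!(alpha > 0 && beta > 0)) {
    stop("beta rate model requires alpha > 0 and beta > 0", call. = FALSE)
  }
  structure(list(kind = "beta", alpha = alpha, beta = beta),
            class = "rate_model")
}

#' @rdname rate_model
#' @export
rate_model_fixed <- function(rates) {
  if (length(rates) < 1L || any(!is.finite(rates) | rates < 0 | rates > 1)) {
    stop("fixed rate model requires rates in [0, 1]", call. = FALSE)
  }
  structure(list(kind = "fixed", rates = as.numeric(rates)),
            class = "rate_model")
}

#' Simulation configuration
#'
#' @param n_items number of items (>= 1).
#' @param n_subjects number of simulated subjects (>= 1).
#' @param rate_model a [rate_model] (default `rate_model_uniform(0.1, 0.9)`).
#' @param seed root integer seed; battery generation uses the derived seed
#'   `derive(seed, 1)` and cohort simulation `derive(seed, 2)`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_items, n_subjects,
                              rate_model = rate_model_uniform(),
                              seed = 1L) {
  n_items <- as.integer(n_items)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_items) || n_items < 1L) stop("n_items must be >= 1", call. = FALSE)
  if (is.na(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  if (!inherits(rate_model, "rate_model")) {
    stop("rate_model must be built with rate_model_uniform/_beta/_fixed",
         call. = FALSE)
  }
  if (rate_model$kind == "fixed" && length(rate_model$rates) != n_items) {
    stop("fixed rate model length must equal n_items", call. = FALSE)
  }
  structure(list(n_items = n_items, n_subjects = n_subjects,
                 rate_model = rate_model, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic battery
#'
#' Draws `n_items` solution rates i.i.d. from the configured rate model.
#' Deterministic given the config: the same seed yields the identical
#' battery.
#'
#' @param config a [simulation_config].
#' @return a [battery] with set label `"synthetic"`.
#' @export
generate_battery <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rm <- config$rate_model
  rates <- if (rm$kind == "fixed") rm$rates else {
    set.seed(derive_seed(config$seed, 1L))
    switch(rm$kind,
           uniform = stats::runif(config$n_items, rm$lo, rm$hi),
           beta = stats::rbeta(config$n_items, rm$alpha, rm$beta))
  }
  battery(sprintf("syn_%03d", seq_len(config$n_items)), "synthetic", rates)
}

#' Simulate a cohort of independent subjects
#'
#' Entry (s, j) of the response matrix is Bernoulli(`p_j`), independent over
#' subjects and items — the exact data-generating model the analytic
#' formulas assume.
#'
#' @param battery a [battery].
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed (set directly; when driving from a
#'   [simulation_config] use `derive_seed(config$seed, 2)` as documented).
#' @return a `response_matrix`: an `n_subjects x n_items` 0/1 integer matrix
#'   with the generating battery attached as attribute `"battery"`.
#' @export
simulate_cohort <- function(battery, n_subjects, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  p <- solution_rates(battery)
  set.seed(as.integer(seed))
  bits <- matrix(stats::rbinom(n_subjects * length(p), 1L, rep(p, each = n_subjects)),
                 nrow = n_subjects, ncol = length(p))
  colnames(bits) <- battery$item_id
  structure(bits, battery = battery, class = c("response_matrix", "matrix", "array"))
}

#' Empirical score PMF of a simulated cohort
#'
#' Normalized histogram of per-subject total scores: the Monte-Carlo
#' counterpart of the exact Poisson-binomial PMF.
#'
#' @param matrix a `response_matrix`.
#' @return a `score_pmf` (estimate; sums to 1 exactly).
#' @export
empirical_score_pmf <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) < 1L) {
    stop("response matrix must be non-empty", call. = FALSE)
  }
  n <- ncol(matrix)
  scores <- rowSums(matrix)
  counts <- tabulate(scores + 1L, nbins = n + 1L)
  new_score_pmf(counts / sum(counts), n)
}

#' Monte-Carlo validation of an analytic profile probability
#'
#' Simulates a cohort and compares the fraction of subjects whose full
#' response vector equals the profile with the analytic occurrence
#' probability, as a binomial z-discrepancy.
#'
#' @param battery a [battery].
#' @param profile an [answer_profile] (or 0/1 vector).
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @return list with `empirical`, `analytic`, `z_discrepancy` (NA when the
#'   analytic probability is 0 or 1, where the discrepancy scale degenerates).
#' @export
validate_profile_probability <- function(battery, profile, n_subjects,
                                         seed = 1L) {
  profile <- check_profile_battery(battery, profile)
  analytic <- profile_probability(battery, profile)
  cohort <- simulate_cohort(battery, n_subjects, seed = seed)
  hits <- colSums(t(cohort) == profile$bits) == length(profile$bits)
  empirical <- mean(hits)
  if (analytic == 0 && empirical > 0) {
    stop("impossible event observed: analytic probability 0 but profile seen",
         call. = FALSE)
  }
  z <- if (analytic > 0 && analytic < 1) {
    (empirical - analytic) / sqrt(analytic * (1 - analytic) / n_subjects)
  } else NA_real_
  list(empirical = empirical, analytic = analytic, z_discrepancy = z)
}

#' Write a response matrix (and its config) to disk
#'
#' @param matrix a `response_matrix`.
#' @param path CSV output path (subjects x items, 0/1).
#' @param config optional [simulation_config] written alongside as
#'   `<path>.config.yml` key-value lines.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(matrix, path, config = NULL) {
  utils::write.csv(as.data.frame(unclass(matrix)), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(config)) {
    rm <- config$rate_model
    lines <- c(
      paste0("n_items: ", config$n_items),
      paste0("n_subjects: ", config$n_subjects),
      paste0("seed: ", config$seed),
      paste0("rate_model: ", rm$kind),
      switch(rm$kind,
             uniform = c(paste0("lo: ", rm$lo), paste0("hi: ", rm$hi)),
             beta = c(paste0("alpha: ", rm$alpha), paste0("beta: ", rm$beta)),
             fixed = paste0("rates: ", paste(rm$rates, collapse = ","))))
    writeLines(lines, paste0(path, ".config.yml"))
  }
  invisible(path)
}
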