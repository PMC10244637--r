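Package: poibench
Title: Exact Poisson-Binomial Benchmarking of Binary Answer Profiles
Version: 0.1.0
Authors@R:
    person("poibench", "developers", email = "poibench@example.org",
           role = c("aut", "cre"))
Description: Benchmarks a single binary answer profile (one respondent's or
    agent's correct/incorrect vector over an item battery) against a human
    reference population described only by per-item solution rates. Computes
    the exact Poisson-binomial distribution of the total score, the occurrence
    probability of any answer combination, and the percentile placement of a
    given combination among all combinations attaining the same total score,
    by direct enumeration or a meet-in-the-middle scheme that scales to tens
    of millions of combinations. Includes the supporting classical statistics
    (two-sided Fisher exact test on a 2x2 table, Wilcoxon rank-sum with
    tie-corrected normal approximation, median/interquartile summaries), a
    synthetic-cohort simulator for Monte-Carlo validation, and a one-command
    pipeline emitting a structured JSON report with plot-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
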