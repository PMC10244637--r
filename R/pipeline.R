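#' @title One-command analysis pipeline
#' @description Reproduces the full benchmarking analysis from built-in
#'   fixtures or user files: per-set and pooled exact score distributions and
#'   modes, conditional placements of the profile, and the supporting
#'   classical comparisons, gathered into a structured, schema-stable report.
#' @name pipeline_cli
NULL

# djb2 string hash, hex-encoded: lightweight content checksum for provenance
content_checksum <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

resolve_battery <- function(source) {
  if (is.null(source)) return(builtin_battery("pooled"))
  if (inherits(source, "battery")) return(source)
  if (is.character(source) && length(source) == 1L) return(read_battery(source))
  stop("battery source must be NULL, a battery, or a file path", call. = FALSE)
}

resolve_profile <- function(source) {
  if (is.null(source)) return(builtin_profile("pooled"))
  if (inherits(source, "answer_profile")) return(source)
  if (is.character(source) && length(source) == 1L) return(read_profile(source))
  if (is.numeric(source)) return(answer_profile(source))
  stop("profile source must be NULL, an answer_profile, or a file path",
       call. = FALSE)
}

analyze_block <- function(bat, bits, q) {
  prof <- answer_profile(bits)
  pmf <- score_pmf_dp(bat)
  mode <- pmf_mode(pmf)
  pl <- placement(bat, prof, q = q)
  list(
    n = n_items(bat),
    profile_score = prof$score,
    pmf = unname(pmf$probs),
    mode = mode$score,
    mode_tied = mode$tied,
    mode_equals_profile = (mode$score == prof$score),
    profile_probability = pl$profile_probability,
    percentile_rank = pl$percentile_rank,
    top_q_threshold = pl$top_q_threshold,
    in_top_q = pl$in_top_q,
    m_combinations = pl$m,
    method = pl$method,
    quantiles = pl$quantiles
  )
}

#' Run the full benchmarking analysis
#'
#' For each set label in the battery (plus a pooled block when there is more
#' than one set) computes the exact score PMF and its mode, compares the
#' mode with the profile's score, and places the profile within its
#' same-score combination distribution. When exactly two sets are present,
#' adds the classical comparisons: Fisher exact test on the two scores,
#' Wilcoxon rank-sum on the solution rates, and median/IQR summaries.
#'
#' @param battery_source `NULL` (built-in pooled fixtures), a [battery], or
#'   a CSV path.
#' @param profile_source `NULL` (built-in profile), an [answer_profile], a
#'   0/1 vector, or a CSV path.
#' @param q top-fraction of interest, in (0, 1) (default 0.05).
#' @return an object of class `analysis_report`: nested list with one block
#'   per set (and `pooled`), a `comparisons` block, and `provenance`
#'   (package version, conventions, battery checksum).
#' @examples
#' \donttest{
#' rep <- run_full_analysis()  # full pooled analysis, ~86.5M combinations
#' rep$sets$practice$in_top_q
#' }
#' @export
run_full_analysis <- function(battery_source = NULL, profile_source = NULL,
                              q = 0.05) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  }
  bat <- resolve_battery(battery_source)
  prof <- resolve_profile(profile_source)
  if (length(prof$bits) != n_items(bat)) {
    stop(sprintf("profile length (%d) does not match battery size (%d)",
                 length(prof$bits), n_items(bat)), call. = FALSE)
  }
  labels <- unique(bat$set_label)
  blocks <- list()
  for (lab in labels) {
    idx <- which(bat$set_label == lab)
    blocks[[lab]] <- analyze_block(validate_battery(as.data.frame(bat)[idx, ]),
                                   prof$bits[idx], q)
  }
  if (length(labels) > 1L) blocks[["pooled"]] <- analyze_block(bat, prof$bits, q)

  comparisons <- NULL
  if (length(labels) == 2L) {
    s <- vapply(labels, function(lab) sum(prof$bits[bat$set_label == lab]),
                integer(1))
    nn <- vapply(labels, function(lab) sum(bat$set_label == lab), integer(1))
    tab <- matrix(c(s[1], s[2], nn[1] - s[1], nn[2] - s[2]), nrow = 2,
                  dimnames = list(labels, c("correct", "incorrect")))
    r1 <- solution_rates(bat)[bat$set_label == labels[1]]
    r2 <- solution_rates(bat)[bat$set_label == labels[2]]
    rs <- ranksum(r1, r2)
    comparisons <- list(
      fisher_p = fisher_exact(tab),
      ranksum_z = rs$z,
      ranksum_p = rs$p,
      medians_iqr = stats::setNames(
        lapply(list(r1, r2), median_iqr), labels)
    )
  }

  structure(list(
    sets = blocks,
    comparisons = comparisons,
    profile = prof$bits,
    battery = as.data.frame(bat)[, c("item_id", "set_label", "solution_rate")],
    provenance = list(
      package = "poibench",
      version = as.character(utils::packageVersion("poibench")),
      q = q,
      battery_checksum = content_checksum(
        sprintf("%s|%s|%.17g", bat$item_id, bat$set_label, bat$solution_rate)),
      conventions = list(
        percentile = "strict-less, relative tie tolerance 1e-9",
        threshold = "nearest-rank upper quantile, membership non-strict (>=)",
        mode_ties = "smallest score, flagged",
        quantile_summary = "midpoint interpolation (h = qn + 0.5)",
        ranksum = "midranks, tie-corrected variance, no continuity correction",
        fisher = "two-sided probability-mass method"
      )
    )
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (lab in names(x$sets)) {
    b <- x$sets[[lab]]
    cat(sprintf(
      "  %-9s score %2d/%2d | mode %2d%s | p = %.3g | pct %.1f | top-%.0f%%: %s\n",
      lab, b$profile_score, b$n, b$mode,
      if (b$mode_equals_profile) " (=score)" else "         ",
      b$profile_probability, b$percentile_rank, 100 * x$provenance$q,
      if (b$in_top_q) "yes" else "no"))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  fisher p = %.4f | ranksum z = %.3f, p = %.4f\n",
                x$comparisons$fisher_p, x$comparisons$ranksum_z,
                x$comparisons$ranksum_p))
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Full double precision is retained in the machine-readable fields (the
#' human-readable `print()` method rounds to 3 significant figures, matching
#' the precision analyses of this kind usually report).
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  for (lab in names(out$sets)) {
    out$sets[[lab]]$quantiles <- as.data.frame(out$sets[[lab]]$quantiles)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export plot-ready figure data from a report
#'
#' * `fig3`: long table `(set, score, probability)` — the exact score PMFs.
#' * `fig4`: the combination-by-item binary matrix of all same-score answer
#'   combinations for one set (rows sum to the profile score); refused when
#'   the combination count exceeds `cap`, as for the pooled set.
#' * `fig5`: down-sampled sorted combination probabilities per set with
#'   5th/50th/95th percentile markers and the profile's probability flagged.
#'
#' @param report an `analysis_report`.
#' @param which one of `"fig3"`, `"fig4"`, `"fig5"`.
#' @param set set label for `fig4` (default: first set block).
#' @param cap largest combination count materialized for `fig4`
#'   (default 1e7).
#' @return a data frame (`fig3`, `fig5`) or binary matrix (`fig4`).
#' @export
export_figure_data <- function(report, which = c("fig3", "fig4", "fig5"),
                               set = NULL, cap = 1e7) {
  which <- match.arg(which)
  blocks <- report$sets
  if (which == "fig3") {
    return(do.call(rbind, lapply(names(blocks), function(lab) {
      data.frame(set = lab, score = seq_along(blocks[[lab]]$pmf) - 1L,
                 probability = blocks[[lab]]$pmf)
    })))
  }
  if (which == "fig4") {
    if (is.null(set)) set <- names(blocks)[1L]
    if (!set %in% names(blocks)) {
      stop("unknown set '", set, "'; available: ",
           paste(names(blocks), collapse = ", "), call. = FALSE)
    }
    b <- blocks[[set]]
    if (b$m_combinations > cap) {
      stop(sprintf(paste0("set '%s' has %.0f same-score combinations, above ",
                          "the cap (%.0f); matrix export is not materialized"),
                   set, b$m_combinations, cap), call. = FALSE)
    }
    idx <- if (set == "pooled") seq_len(nrow(report$battery))
    else which(report$battery$set_label == set)
    n <- length(idx)
    k <- b$profile_score
    cb <- utils::combn(n, k)
    mat <- matrix(0L, nrow = ncol(cb), ncol = n,
                  dimnames = list(NULL, report$battery$item_id[idx]))
    mat[cbind(rep(seq_len(ncol(cb)), each = k), as.vector(cb))] <- 1L
    return(mat)
  }
  # fig5
  do.call(rbind, lapply(names(blocks), function(lab) {
    qs <- blocks[[lab]]$quantiles
    data.frame(set = lab, rank = qs$rank, probability = qs$probability,
               marker = qs$marker,
               is_profile_probability = FALSE,
               stride = attr(qs, "stride"))
  })) -> out
  prof_rows <- do.call(rbind, lapply(names(blocks), function(lab) {
    b <- blocks[[lab]]
    data.frame(set = lab, rank = NA_real_,
               probability = b$profile_probability, marker = "profile",
               is_profile_probability = TRUE, stride = NA_real_)
  }))
  rbind(out, prof_rows)
}
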