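#' Item battery with normative per-item solution rates
#'
#' A battery is an ordered set of items, each carrying the proportion of a
#' human reference sample that solved it (its solution rate `p_j`) and a set
#' label. Item order is significant: answer profiles are matched to items
#' positionally.
#'
#' @param item_id character vector of unique item identifiers.
#' @param set_label character vector of set labels (e.g. `"practice"`,
#'   `"transfer"`), recycled if length 1.
#' @param solution_rate numeric vector of per-item solution rates in
#'   `[0, 1]`.
#' @return An object of class `battery`: a `data.frame` with columns
#'   `item_id`, `set_label`, `solution_rate`.
#' @examples
#' b <- battery(c("q1", "q2"), "demo", c(0.5, 0.25))
#' n_items(b)
#' @export
battery <- function(item_id, set_label, solution_rate) {
  df <- data.frame(
    item_id = as.character(item_id),
    set_label = as.character(rep_len(set_label, length(item_id))),
    solution_rate = as.numeric(solution_rate),
    stringsAsFactors = FALSE
  )
  validate_battery(df)
}

#' Validate (and bless) a battery data frame
#'
#' @param x a `data.frame` with columns `item_id`, `set_label`,
#'   `solution_rate`.
#' @return `x` with class `battery` prepended, invisibly checked.
#' @export
validate_battery <- function(x) {
  required <- c("item_id", "set_label", "solution_rate")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("battery is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 1L) stop("battery must contain at least one item", call. = FALSE)
  dup <- duplicated(x$item_id)
  if (any(dup)) {
    stop("duplicate item_id: ", paste(unique(x$item_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x$solution_rate) |
                 x$solution_rate < 0 | x$solution_rate > 1)
  if (length(bad) > 0L) {
    stop("solution_rate outside [0, 1] in row(s) ",
         paste(bad, collapse = ", "), " (item ",
         paste(x$item_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- unique(c("battery", class(x)))
  x
}

#' Number of items in a battery
#' @param battery a `battery`.
#' @return integer item count.
#' @export
n_items <- function(battery) nrow(battery)

#' Solution-rate vector of a battery
#' @param battery a `battery`.
#' @return numeric vector of per-item rates, in item order.
#' @export
solution_rates <- function(battery) battery$solution_rate

#' @export
print.battery <- function(x, ...) {
  cat(sprintf("<battery> %d items (%s)\n", nrow(x),
              paste(unique(x$set_label), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Binary answer profile over a battery
#'
#' One respondent's (or agent's) answers: 1 = correct, 0 = incorrect, one bit
#' per battery item in item order. The total score is the number of 1s.
#'
#' @param bits vector coercible to 0/1 integers.
#' @return An object of class `answer_profile` with elements `bits`
#'   (integer vector) and `score` (integer).
#' @examples
#' answer_profile(c(1, 0, 1))$score
#' @export
answer_profile <- function(bits) {
  b <- as.integer(bits)
  if (length(b) < 1L || anyNA(b) || !all(b %in% c(0L, 1L))) {
    stop("profile bits must be a non-empty vector of 0/1 values", call. = FALSE)
  }
  structure(list(bits = b, score = sum(b)), class = "answer_profile")
}

#' @export
print.answer_profile <- function(x, ...) {
  cat(sprintf("<answer_profile> score %d/%d: [%s]\n", x$score,
              length(x$bits), paste(x$bits, collapse = ", ")))
  invisible(x)
}

check_profile_battery <- function(battery, profile) {
  if (!inherits(profile, "answer_profile")) profile <- answer_profile(profile)
  if (length(profile$bits) != nrow(battery)) {
    stop(sprintf("profile length (%d) does not match battery size (%d)",
                 length(profile$bits), nrow(battery)), call. = FALSE)
  }
  profile
}

# ---- built-in study fixtures ------------------------------------------------

# 15 verbal insight "practice" items: normative solution rates of a 20-subject
# human sample, stored verbatim at printed precision (several rates imply
# non-uniform per-item denominators; they are taken as printed, not re-derived).
practice_rates <- c(0.50, 0.211, 0.75, 0.20, 0.65, 0.65, 0.19, 0.55,
                    0.65, 0.10, 0.556, 0.579, 0.286, 0.50, 0.60)
transfer_rates <- c(0.40, 0.45, 0.364, 0.40, 0.30, 0.30, 0.421, 0.35,
                    0.30, 0.318, 0.35, 0.368, 0.30, 0.40, 0.318)
practice_bits <- c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)
transfer_bits <- c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L)

#' Built-in item batteries from the reference study
#'
#' Returns the normative solution-rate batteries shipped with the package:
#' 15 practice items, 15 transfer items, or their 30-item pooled
#' concatenation (practice items first, order preserved).
#'
#' @param which one of `"practice"`, `"transfer"`, `"pooled"`.
#' @return a [battery].
#' @examples
#' builtin_battery("practice")$solution_rate[1]  # 0.50
#' @export
builtin_battery <- function(which = c("practice", "transfer", "pooled")) {
  which <- match.arg(which)
  p <- battery(sprintf("practice_%02d", seq_along(practice_rates)),
               "practice", practice_rates)
  t <- battery(sprintf("transfer_%02d", seq_along(transfer_rates)),
               "transfer", transfer_rates)
  switch(which,
         practice = p,
         transfer = t,
         pooled = validate_battery(rbind(p, t)))
}

#' Built-in ChatGPT answer profiles from the reference study
#'
#' The binary correct/incorrect vectors scored against the built-in
#' batteries: scores 7/15 (practice), 5/15 (transfer), 12/30 (pooled).
#'
#' @param which one of `"practice"`, `"transfer"`, `"pooled"`.
#' @return an [answer_profile].
#' @export
builtin_profile <- function(which = c("practice", "transfer", "pooled")) {
  which <- match.arg(which)
  switch(which,
         practice = answer_profile(practice_bits),
         transfer = answer_profile(transfer_bits),
         pooled = answer_profile(c(practice_bits, transfer_bits)))
}

# ---- tabular I/O ------------------------------------------------------------

parse_rate <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (anyNA(out)) {
    stop("unparseable solution_rate value(s): ",
         paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out[pct] <- out[pct] / 100
  out
}

#' Read a battery from a CSV file
#'
#' Expects a header with columns `item_id`, `set_label`, `solution_rate`
#' (and optionally `answer` for an accompanying profile, ignored here — see
#' [read_profile()]). Rates may be decimals (`0.50`) or percent strings
#' (`"50%"`); output is always decimal proportions.
#'
#' @param source path to a CSV file (or connection).
#' @return a [battery].
#' @seealso [write_battery()], [read_profile()]
#' @export
read_battery <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("item_id", "set_label", "solution_rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("battery file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$solution_rate <- parse_rate(df$solution_rate)
  validate_battery(df[, intersect(c(required, "answer"), names(df))])
}

#' Write a battery (optionally with a profile) to CSV
#'
#' @param battery a [battery].
#' @param path output file path.
#' @param profile optional [answer_profile] written as an `answer` column.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path, profile = NULL) {
  df <- as.data.frame(battery)[, c("item_id", "set_label", "solution_rate")]
  if (!is.null(profile)) {
    profile <- check_profile_battery(battery, profile)
    df$answer <- profile$bits
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an answer profile from a CSV file
#'
#' Accepts either a battery CSV carrying an `answer` column (bit per item,
#' battery item order) or a single-column CSV of 0/1 bits.
#'
#' @param source path to a CSV file.
#' @return an [answer_profile].
#' @export
read_profile <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  col <- if ("answer" %in% names(df)) df$answer else if (ncol(df) == 1L) df[[1L]]
  else stop("profile file must have an 'answer' column or a single column",
            call. = FALSE)
  answer_profile(col)
}
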