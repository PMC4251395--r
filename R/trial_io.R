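#' Read randomized-trial summary data
#'
#' Reads a CSV of two-arm trial summaries, one row per randomized trial.
#' Required columns are `trial_id`, `n_control`, `events_control`,
#' `n_treated`, `events_treated`; an optional `followup_years` column
#' records the observation period and defaults to 1 (one-year risks, the
#' usual convention for post-myocardial-infarction mortality data).
#'
#' @param path Path to a CSV file with the header described above.
#' @return A `data.frame` with one validated row per trial: integer counts,
#'   positive arm sizes, `0 <= events <= n` in both arms, unique trial ids.
#' @seealso [risk_pairs()] to map trials to points on the L'Abbe plane.
#' @export
read_trial_summaries <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_user("`path` must be a single file path")
  }
  if (!file.exists(path)) stop_user("trial summary file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "n_control", "events_control",
                "n_treated", "events_treated")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_user("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"followup_years" %in% names(df)) df$followup_years <- 1
  df$followup_years[is.na(df$followup_years)] <- 1
  for (col in setdiff(required, "trial_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(v != round(v))) {
      stop_user("column ", col, " must contain non-negative integer counts")
    }
    df[[col]] <- as.integer(v)
  }
  df <- df[, c(required, "followup_years")]
  validate_trial_summaries(df)
  df
}

# Invariant checks shared by the reader and by in-memory constructors.
validate_trial_summaries <- function(df) {
  if (anyDuplicated(df$trial_id)) {
    dup <- df$trial_id[duplicated(df$trial_id)][1L]
    stop_user("duplicate trial_id: ", dup)
  }
  bad_n <- df$n_control <= 0L | df$n_treated <= 0L
  if (any(bad_n)) {
    stop_user("trial ", df$trial_id[bad_n][1L], ": arm sizes must be positive")
  }
  bad_c <- df$events_control < 0L | df$events_control > df$n_control
  if (any(bad_c)) {
    stop_user("trial ", df$trial_id[bad_c][1L],
              ": events_control must lie in [0, n_control]")
  }
  bad_t <- df$events_treated < 0L | df$events_treated > df$n_treated
  if (any(bad_t)) {
    stop_user("trial ", df$trial_id[bad_t][1L],
              ": events_treated must lie in [0, n_treated]")
  }
  invisible(df)
}

#' Map trial summaries to weighted points on the L'Abbe plane
#'
#' Converts each trial's event counts to the control-arm risk
#' `rc = events_control / n_control` and treated-arm risk
#' `rt = events_treated / n_treated`, with a fitting weight per trial.
#'
#' Weighting schemes:
#' \describe{
#'   \item{`inverse_variance`}{`1 / (rt (1 - rt) / n_treated)` — the inverse
#'     binomial variance of the response in a regression of Rt on Rc. When a
#'     treated arm has 0 or `n` events a continuity correction
#'     (`events + 0.5`, `n + 1`) is applied inside the weight so it stays
#'     finite; the reported `rt` itself is the uncorrected ratio.}
#'   \item{`total_n`}{the total number of randomized subjects.}
#'   \item{`equal`}{weight 1 for every trial.}
#' }
#'
#' @param trials A trial summary `data.frame` as returned by
#'   [read_trial_summaries()].
#' @param weighting One of `"inverse_variance"` (default), `"total_n"`,
#'   `"equal"`.
#' @return A `data.frame` with columns `trial_id`, `rc`, `rt`, `weight`;
#'   `rc` and `rt` always lie in `[0, 1]` and weights are positive.
#' @export
risk_pairs <- function(trials,
                       weighting = c("inverse_variance", "total_n", "equal")) {
  weighting <- match.arg(weighting)
  validate_trial_summaries(trials)
  rc <- trials$events_control / trials$n_control
  rt <- trials$events_treated / trials$n_treated
  weight <- switch(weighting,
    equal = rep(1, nrow(trials)),
    total_n = trials$n_control + trials$n_treated,
    inverse_variance = {
      e <- trials$events_treated
      n <- trials$n_treated
      deg <- e == 0L | e == n
      e_cc <- ifelse(deg, e + 0.5, e)
      n_cc <- ifelse(deg, n + 1, n)
      p <- e_cc / n_cc
      n_cc / (p * (1 - p))
    }
  )
  out <- data.frame(trial_id = trials$trial_id, rc = rc, rt = rt,
                    weight = weight, stringsAsFactors = FALSE)
  attr(out, "weighting") <- weighting
  out
}

#' Write or read an L'Abbe-plane table
#'
#' `write_labbe_table()` exports `(rc, rt, weight)` points to CSV for
#' plotting or refitting; `read_labbe_table()` reads them back. The round
#' trip is lossless to at least 12 significant digits.
#'
#' @param pairs A nonempty `data.frame` with numeric columns `rc`, `rt` and
#'   optionally `weight` (defaulting to 1).
#' @param path Output (or input) CSV path.
#' @return `write_labbe_table()` returns `path` invisibly;
#'   `read_labbe_table()` returns the pairs `data.frame`.
#' @export
write_labbe_table <- function(pairs, path) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop_user("`pairs` must be a nonempty data.frame of risk pairs")
  }
  if (!all(c("rc", "rt") %in% names(pairs))) {
    stop_user("`pairs` must have columns rc and rt")
  }
  if (!"weight" %in% names(pairs)) pairs$weight <- 1
  bad <- pairs$rc < 0 | pairs$rc > 1 | pairs$rt < 0 | pairs$rt > 1
  if (any(bad)) stop_user("rc and rt must lie in [0, 1]")
  out <- data.frame(
    rc = format(pairs$rc, digits = 15, scientific = FALSE, trim = TRUE),
    rt = format(pairs$rt, digits = 15, scientific = FALSE, trim = TRUE),
    weight = format(pairs$weight, digits = 15, scientific = FALSE, trim = TRUE)
  )
  ok <- try(suppressWarnings(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)),
    silent = TRUE)
  if (inherits(ok, "try-error")) stop_user("cannot write to: ", path)
  invisible(path)
}

#' @rdname write_labbe_table
#' @export
read_labbe_table <- function(path) {
  if (!file.exists(path)) stop_user("L'Abbe table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rc", "rt", "weight")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_user("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df[need]
}
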