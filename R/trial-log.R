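trial_log_columns <- function() {
  c("observer_id", "strategy", "condition", "conflict_mm", "reference_mm",
    "comparison_mm", "delta_mm", "response_comp_larger", "block",
    "trial_index")
}

#' Write a trial log as CSV
#'
#' One row per trial with a mandatory header.  Columns: `observer_id`,
#' `strategy`, `condition`, `conflict_mm`, `reference_mm`,
#' `comparison_mm`, `delta_mm`, `response_comp_larger`, `block`,
#' `trial_index`.
#'
#' @param trials Trial data frame (as produced by
#'   `run_experiment(..., keep_trials = TRUE)`), or an `"experiment_data"`
#'   object carrying one.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  if (inherits(trials, "experiment_data")) trials <- trials$trials
  if (is.null(trials)) stop("no trial-level records to write; rerun with ",
                            "keep_trials = TRUE", call. = FALSE)
  missing_cols <- setdiff(trial_log_columns(), names(trials))
  if (length(missing_cols) > 0)
    stop("trial log missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(trials[trial_log_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads a CSV trial log (synthetic or human origin), checking the header
#' and rejecting malformed rows with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated trial data frame.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse trial log ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(trial_log_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("trial log ", path, " is missing required header column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$response_comp_larger <- as.logical(df$response_comp_larger)
  num_cols <- c("conflict_mm", "reference_mm", "comparison_mm", "delta_mm")
  bad <- !stats::complete.cases(df[c("observer_id", "condition", num_cols,
                                     "response_comp_larger")]) |
    !Reduce(`&`, lapply(df[num_cols], is.finite))
  if (any(bad))
    stop("malformed trial log rows (line numbers incl. header): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  df
}

#' Aggregate a trial log into per-condition counts
#'
#' Pools one observer's trials across blocks into [condition_data()]
#' objects keyed by condition label.
#'
#' @param trials Trial data frame (one observer).
#' @return Named list of [condition_data()].
#' @export
condition_data_from_log <- function(trials) {
  out <- lapply(split(trials, trials$condition), function(d)
    condition_data_from_trials(d$delta_mm, d$response_comp_larger))
  out[intersect(unique(trials$condition), names(out))]
}
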