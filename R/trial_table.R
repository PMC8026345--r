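# Canonical tidy trial table: one row per scheduled pointing trial.

trial_table_columns <- c("subject_id", "age_group", "block", "trial_in_block",
                         "intersection", "direction", "target", "trial_kind",
                         "abs_error", "signed_error", "response_time",
                         "missing")

#' Validate a trial table
#'
#' Checks every row of a tidy per-trial table against the invariants of the
#' canonical record: absolute errors in \[0, 180\] degrees, signed errors in
#' (-180, 180\] with `abs_error == |signed_error|`, response times in
#' (0, timeout\], `missing == TRUE` exactly when the error is absent, and
#' block indices within the schedule.
#'
#' @param trials data frame with the canonical columns.
#' @param spec optional [schedule_spec()]; enables block-range and timeout
#'   checks.
#' @return The validated table (invisibly), with rows ordered by subject,
#'   block and trial.
#' @export
validate_trial_table <- function(trials, spec = NULL) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols) > 0L) {
    stopf("trial table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stopf("invalid trial table: %s (first offending row: %d)", what, idx[1])
    }
  }
  obs <- !is.na(trials$abs_error)
  bad_row(obs & (trials$abs_error < 0 | trials$abs_error > 180),
          "abs_error outside [0, 180]")
  bad_row(!is.na(trials$signed_error) &
            (trials$signed_error <= -180 | trials$signed_error > 180),
          "signed_error outside (-180, 180]")
  both <- obs & !is.na(trials$signed_error)
  bad_row(both & abs(abs(trials$signed_error) - trials$abs_error) > 1e-8,
          "abs_error != |signed_error|")
  bad_row(xor(trials$missing, !obs), "missing flag inconsistent with abs_error")
  bad_row(!is.na(trials$response_time) & trials$response_time <= 0,
          "response_time must be positive")
  bad_row(!trials$age_group %in% c("young", "old"), "age_group not young/old")
  bad_row(!trials$trial_kind %in% c("retrieval", "control"),
          "trial_kind not retrieval/control")
  if (!is.null(spec)) {
    bad_row(trials$block < 1L | trials$block > spec$blocks,
            sprintf("block outside 1..%d", spec$blocks))
    bad_row(!is.na(trials$response_time) & trials$response_time > spec$timeout,
            "response_time exceeds timeout")
  }
  trials <- trials[order(trials$subject_id, trials$block,
                         trials$trial_in_block), ]
  rownames(trials) <- NULL
  invisible(trials)
}

#' Read / write the canonical trial CSV
#'
#' UTF-8 CSV with a header containing exactly the canonical columns; absent
#' numeric values (missing trials) are empty cells. `read_trial_table`
#' validates every row and returns records deterministically ordered by
#' (subject, block, trial_in_block).
#'
#' @param path file path.
#' @param spec optional [schedule_spec()] used for validation.
#' @return A validated trial data frame.
#' @export
read_trial_table <- function(path, spec = NULL) {
  if (!file.exists(path)) stopf("trial table not found: %s", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character"))
  trials$missing <- as.logical(trials$missing)
  validate_trial_table(trials, spec)
}

#' @rdname read_trial_table
#' @param trials trial data frame to write.
#' @export
write_trial_table <- function(trials, path) {
  trials <- validate_trial_table(trials)
  utils::write.csv(trials[, trial_table_columns], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-block summaries of observed performance
#'
#' Block mean absolute error over observed retrieval trials only, with
#' observed/missing counts. The block mean is the location used by the
#' model's missing-trial prior.
#'
#' @param trials validated trial table (one or more subjects).
#' @return Data frame with `subject_id`, `block`, `block_mean_error`,
#'   `n_observed`, `n_missing`.
#' @export
block_summaries <- function(trials) {
  retr <- trials[trials$trial_kind == "retrieval", ]
  out <- do.call(rbind, lapply(split(retr, list(retr$subject_id, retr$block),
                                     drop = TRUE), function(d) {
    obs <- !is.na(d$abs_error)
    data.frame(subject_id = d$subject_id[1], block = d$block[1],
               block_mean_error = if (any(obs)) mean(d$abs_error[obs]) else NA_real_,
               n_observed = sum(obs), n_missing = sum(!obs),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subject_id, out$block), ]
  rownames(out) <- NULL
  out
}
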