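TRIAL_COLUMNS <- c("subject_id", "session", "trial", "cue", "action",
                   "outcome", "true_state", "reversal_flag")

#' Write trial logs to CSV
#'
#' One row per trial with columns `subject_id`, `session`, `trial`, `cue`,
#' `action`, `outcome`, `true_state`, `reversal_flag` (codes 1/2; the true
#' latent context may be NA for real data).
#'
#' @param trials Trial data frame (a `subject_id` column is added if absent)
#'   or a `seqinfer_cohort`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "seqinfer_cohort")) trials <- trials$trials
  if (!"subject_id" %in% names(trials)) trials$subject_id <- "sub01"
  if (!"true_state" %in% names(trials)) trials$true_state <- NA_integer_
  if (!"reversal_flag" %in% names(trials)) trials$reversal_flag <- NA
  write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate trial logs
#'
#' Reads a CSV written in the [write_trials()] layout, checks the schema
#' (mandatory header, codes in {1, 2}, no duplicate subject/trial pairs) and
#' returns the records sorted by subject and trial.
#'
#' @param path CSV file path.
#' @return A validated trial data frame.
#' @export
read_trials <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_data(paste("cannot parse trial CSV:",
                                                     conditionMessage(e))))
  need <- c("subject_id", "trial", "cue", "action", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_data(paste("trial CSV is missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) stop_data("trial CSV contains no rows")
  for (col in c("cue", "action", "outcome")) {
    bad <- which(!df[[col]] %in% c(1L, 2L))
    if (length(bad) > 0)
      stop_data(sprintf("column `%s` has an invalid code at data row %d", col, bad[1]))
    df[[col]] <- as.integer(df[[col]])
  }
  if ("true_state" %in% names(df)) {
    bad <- which(!(is.na(df$true_state) | df$true_state %in% c(1L, 2L)))
    if (length(bad) > 0)
      stop_data(sprintf("column `true_state` has an invalid code at data row %d", bad[1]))
  }
  dup <- duplicated(df[, c("subject_id", "trial")])
  if (any(dup))
    stop_data(sprintf("duplicate (subject, trial) pair at data row %d", which(dup)[1]))
  df[order(df$subject_id, df$trial), , drop = FALSE]
}

#' Write a cohort manifest as JSON
#'
#' Records, per subject, the generating model, its parameters and the
#' simulation seed -- the ground truth for recovery studies.
#'
#' @param cohort A `seqinfer_cohort`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  if (!inherits(cohort, "seqinfer_cohort")) stop_config("`cohort` must be a seqinfer_cohort")
  manifest <- lapply(cohort$manifest, function(m) {
    m$parameters <- m$parameters[!vapply(m$parameters, is.null, logical(1))]
    m
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path JSON path written by [write_manifest()].
#' @return A named list of per-subject `model`, `parameters`, `seed`.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Export a belief trace as CSV
#'
#' Writes the per-trial predictive belief, posterior belief and action
#' probability of a [run_inference()] result, e.g. for reversal-locked
#' averaging plots.
#'
#' @param inference A `seq_inference` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_belief_trace <- function(inference, path) {
  if (!inherits(inference, "seq_inference"))
    stop_config("`inference` must come from run_inference()")
  write.csv(inference$trace[, c("trial", "pred_p1", "post_p1", "p_action1")],
            path, row.names = FALSE)
  invisible(path)
}
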