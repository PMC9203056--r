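#' Derive trial outcome labels
#'
#' Outcome is a pure function of trial type, response hand, RT and required
#' hand: go trials are `go_correct` / `go_error` (wrong hand) /
#' `go_omission` (no response); stop trials are `stop_success` (no response)
#' or `stop_fail`.
#'
#' @param trial_type character, `"go"` or `"stop"`.
#' @param response_hand character, `"left"`, `"right"` or `"none"`.
#' @param rt numeric RT in ms (`NA` when no response).
#' @param required_hand character, `"left"` or `"right"`.
#' @return character vector of outcome labels.
#' @export
deriveOutcome <- function(trial_type, response_hand, rt, required_hand) {
  responded <- response_hand != "none" & !is.na(response_hand)
  ifelse(trial_type == "go",
         ifelse(!responded, "go_omission",
                ifelse(response_hand == required_hand,
                       "go_correct", "go_error")),
         ifelse(responded, "stop_fail", "stop_success"))
}

#' Validate a trial table
#'
#' Checks the structural invariants of a trial table: SSD present exactly on
#' stop trials, RT present exactly when a response hand is recorded, RTs
#' within the response window, and recomputes the `outcome` column.
#'
#' @param trials data.frame with columns `trial_id`, `block`, `trial_type`,
#'   `go_onset` (s), `ssd` (ms, `NA` on go trials), `response_hand`, `rt`
#'   (ms), `required_hand`.
#' @param response_window maximum valid RT in ms (default 1000).
#' @return the trial table with a derived `outcome` column.
#' @export
validateTrialTable <- function(trials, response_window = 1000) {
  req <- c("trial_id", "block", "trial_type", "go_onset", "ssd",
           "response_hand", "rt", "required_hand")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(trials$trial_type %in% c("go", "stop")))
    stop("trial_type must be 'go' or 'stop'", call. = FALSE)
  if (any(trials$trial_type == "stop" & is.na(trials$ssd)))
    stop("stop trial with missing SSD", call. = FALSE)
  if (any(trials$trial_type == "go" & !is.na(trials$ssd)))
    stop("go trial with an SSD", call. = FALSE)
  responded <- trials$response_hand != "none"
  if (any(responded & is.na(trials$rt)))
    stop("response without RT", call. = FALSE)
  if (any(!responded & !is.na(trials$rt)))
    stop("rt without response hand", call. = FALSE)
  if (any(trials$rt > response_window, na.rm = TRUE))
    stop(sprintf("RT beyond the %g ms response window", response_window),
         call. = FALSE)
  trials$outcome <- deriveOutcome(trials$trial_type, trials$response_hand,
                                  trials$rt, trials$required_hand)
  trials
}

#' Read a trial/event table
#'
#' Reads a tab-separated trial table (one row per trial; go-signal onsets in
#' seconds on the recording clock, SSD and RT in milliseconds; empty fields
#' mark missing values), validates it and derives outcome labels.
#'
#' @inheritParams validateTrialTable
#' @param path path to the tab-separated file.
#' @return validated trial table with an `outcome` column.
#' @export
readTrialTable <- function(path, response_window = 1000) {
  trials <- utils::read.delim(path, na.strings = c("NA", ""),
                              colClasses = c(trial_type = "character",
                                             response_hand = "character",
                                             required_hand = "character"))
  validateTrialTable(trials, response_window = response_window)
}

#' Write a trial table
#'
#' Tab-separated, missing values as empty fields (never sentinel numbers);
#' round-trips losslessly through [readTrialTable()].
#'
#' @param trials a validated trial table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
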