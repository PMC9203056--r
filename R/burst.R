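#' Burst-detection configuration
#'
#' A burst is present in a trial when any z-scored envelope sample within the
#' search window exceeds the threshold (default 1.2 z, held constant across
#' participants because the envelopes are standardized). Onset tracing walks
#' backwards from the peak until a continuous sub-threshold run of
#' `onset_run_ms` (default 8 ms) is found.
#'
#' @param threshold detection threshold in z units.
#' @param onset_run_ms length of the sub-threshold run terminating the
#'   backward onset trace, in ms.
#' @param search_window numeric length-2, window in s (relative to go onset)
#'   eligible for detection. Defaults to the post-go portion so baseline
#'   noise cannot trigger detection.
#' @return a list of class `detection_config`.
#' @export
detectionConfig <- function(threshold = 1.2, onset_run_ms = 8,
                            search_window = c(0, 1.6)) {
  stopifnot(threshold > 0, onset_run_ms > 0,
            search_window[1] < search_window[2])
  structure(list(threshold = threshold, onset_run_ms = onset_run_ms,
                 search_window = search_window),
            class = "detection_config")
}

.searchCols <- function(time, window) {
  idx <- which(time >= window[1] - 1e-12 & time <= window[2] + 1e-12)
  if (!length(idx)) stop("empty search window", call. = FALSE)
  idx
}

#' Detect the EMG burst peak in one epoch
#'
#' A burst is detected iff any sample of the z-scored envelope within the
#' search window exceeds the threshold. The peak is the argmax over the full
#' search window (earliest index on exact ties) and `peak_amp` its value.
#'
#' @param trace numeric vector, one z-scored envelope epoch.
#' @param time time axis in s relative to go onset.
#' @param config a [detectionConfig()].
#' @return list with `detected`, `peak_index` (index into `trace`),
#'   `peak_amp`.
#' @export
detectPeak <- function(trace, time, config = detectionConfig()) {
  cols <- .searchCols(time, config$search_window)
  seg <- trace[cols]
  if (all(is.na(seg)))
    return(list(detected = FALSE, peak_index = NA_integer_,
                peak_amp = NA_real_))
  j <- which.max(seg)  # earliest index wins ties
  detected <- any(seg > config$threshold, na.rm = TRUE)
  list(detected = detected,
       peak_index = if (detected) cols[j] else NA_integer_,
       peak_amp = if (detected) seg[j] else NA_real_)
}

#' Trace the burst onset backwards from the peak
#'
#' Walks backwards in time from the peak until at least
#' `onset_run_ms` of consecutive samples lie below the threshold (4 samples
#' at 500 Hz for the 8 ms default); the onset is the first supra-threshold
#' sample after that run, i.e. the earliest sample of the detected burst.
#' If no such run exists before the start of the search window, the onset is
#' the window start and a warning flag is raised.
#'
#' @param trace numeric vector, one z-scored envelope epoch.
#' @param time time axis in s.
#' @param peak_index index of the detected peak.
#' @param rate sampling rate in Hz.
#' @param config a [detectionConfig()].
#' @return list with `onset_index` and logical `warn`.
#' @export
traceOnset <- function(trace, time, peak_index, rate,
                       config = detectionConfig()) {
  if (is.na(peak_index) || peak_index < 1L || peak_index > length(trace))
    stop("peak index outside the epoch", call. = FALSE)
  cols <- .searchCols(time, config$search_window)
  first <- cols[1]
  n_run <- max(1L, round(config$onset_run_ms / 1000 * rate))
  run <- 0L
  i <- peak_index - 1L
  while (i >= first) {
    if (!is.na(trace[i]) && trace[i] < config$threshold) {
      run <- run + 1L
      if (run >= n_run)
        return(list(onset_index = i + run, warn = FALSE))
    } else {
      run <- 0L
    }
    i <- i - 1L
  }
  list(onset_index = first, warn = TRUE)
}

#' Stop-lock a go-locked peak latency
#'
#' Re-expresses a go-locked peak latency relative to stop-signal onset by
#' subtracting the SSD. The result may be negative (burst peaked before the
#' stop signal); such trials are flagged downstream, not dropped here.
#'
#' @param peak_go peak latency in ms from go onset.
#' @param ssd stop signal delay in ms.
#' @return peak latency in ms from stop onset.
#' @export
stopLock <- function(peak_go, ssd) {
  if (any(is.na(ssd)))
    stop("SSD absent; stop-locking applies to stop trials only",
         call. = FALSE)
  peak_go - ssd
}

#' Classify a trial's EMG type
#'
#' Go trials with a detected burst are `go_emg`; unsuccessful stop trials
#' with a burst are `ustop_emg`; successful stop trials with a burst are
#' `premg` (partial-response EMG); trials without a burst are `none`.
#'
#' @param outcome trial outcome label (see [deriveOutcome()]).
#' @param detected logical, burst detected.
#' @return character EMG class.
#' @export
classifyTrialEmg <- function(outcome, detected) {
  ifelse(!detected, "none",
         ifelse(outcome %in% c("go_correct", "go_error", "go_omission"),
                "go_emg",
                ifelse(outcome == "stop_fail", "ustop_emg", "premg")))
}

#' Extract the burst table from z-scored epochs
#'
#' Runs peak detection, backward onset tracing, stop-locking and EMG-class
#' labeling on every non-rejected trial, and derives the per-trial measures:
#' `onset_go` / `peak_go` (ms from go onset), `peak_stop` (ms from stop
#' onset, stop trials), `peak_amp` (z), `motor_time` (RT minus EMG onset),
#' `rise_time` (peak minus onset) and `auc` (cumulative sum of envelope
#' amplitudes from onset to peak). Trials whose prEMG peak precedes the stop
#' signal are flagged (`pre_stop_peak`), not removed; exclusion happens only
#' in the single-trial preparation.
#'
#' @param epochs an [EpochSet-class] at stage `"zscored"`.
#' @param config a [detectionConfig()].
#' @return data.frame, one row per non-rejected trial.
#' @export
extractBursts <- function(epochs, config = detectionConfig()) {
  if (epochs@stage != "zscored")
    stop("burst detection runs on z-scored envelopes", call. = FALSE)
  time <- epochs@time
  rate <- epochs@rate
  keep <- which(is.na(epochs@rejected))
  tr <- epochs@trials
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    r <- keep[k]
    trace <- epochs@data[r, ]
    pk <- detectPeak(trace, time, config)
    onset_go <- peak_go <- peak_stop <- motor <- rise <- auc <- NA_real_
    warn <- FALSE
    if (pk$detected) {
      on <- traceOnset(trace, time, pk$peak_index, rate, config)
      warn <- on$warn
      onset_go <- time[on$onset_index] * 1000
      peak_go  <- time[pk$peak_index] * 1000
      if (tr$trial_type[r] == "stop")
        peak_stop <- stopLock(peak_go, tr$ssd[r])
      if (!is.na(tr$rt[r])) motor <- tr$rt[r] - onset_go
      rise <- peak_go - onset_go
      auc <- sum(trace[on$onset_index:pk$peak_index])
    }
    out[[k]] <- data.frame(
      trial_id = tr$trial_id[r], block = tr$block[r],
      trial_type = tr$trial_type[r], outcome = tr$outcome[r],
      hand = tr$hand[r], ssd = tr$ssd[r], rt = tr$rt[r],
      detected = pk$detected, onset_go = onset_go, peak_go = peak_go,
      peak_stop = peak_stop, peak_amp = pk$peak_amp,
      motor_time = motor, rise_time = rise, auc = auc,
      onset_warn = warn)
  }
  bursts <- do.call(rbind, out)
  bursts$emg_class <- classifyTrialEmg(bursts$outcome, bursts$detected)
  bursts$pre_stop_peak <- !is.na(bursts$peak_stop) & bursts$peak_stop < 0
  bursts
}
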