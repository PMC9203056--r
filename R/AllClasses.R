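#' @import methods
NULL

#' Continuous multichannel EMG recording
#'
#' Container for a continuous bipolar surface-EMG recording: an amplitude
#' matrix (channels x samples, microvolts), its sampling rate, channel labels
#' with a channel-to-hand assignment, event markers on the recording clock,
#' and free-form provenance metadata.
#'
#' @slot samples numeric matrix, channels x samples, in microvolts.
#' @slot rate sampling frequency in Hz.
#' @slot channels character vector of channel labels (rownames of `samples`).
#' @slot hands named character vector mapping channel label to
#'   `"left"`/`"right"`.
#' @slot events data.frame with columns `time` (seconds from recording start)
#'   and `code` (character marker).
#' @slot meta list of provenance fields (source file, units, filter history).
#'
#' @seealso [readContinuousRecording()], [bandpassFilter()],
#'   [resampleRecording()], [epochRecording()]
#' @export
setClass("ContinuousRecording",
  representation(
    samples  = "matrix",
    rate     = "numeric",
    channels = "character",
    hands    = "character",
    events   = "data.frame",
    meta     = "list"
  ),
  prototype(
    samples  = matrix(numeric(0), nrow = 0, ncol = 0),
    rate     = 1,
    channels = character(0),
    hands    = character(0),
    events   = data.frame(time = numeric(0), code = character(0)),
    meta     = list()
  )
)

setValidity("ContinuousRecording", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (nrow(object@samples) != length(object@channels))
    msg <- c(msg, "one channel label per row of 'samples' required")
  if (length(object@hands) &&
      !all(object@hands %in% c("left", "right")))
    msg <- c(msg, "hand assignments must be 'left' or 'right'")
  if (length(object@hands) && is.null(names(object@hands)))
    msg <- c(msg, "'hands' must be named by channel label")
  dur <- recordingDuration(object)
  ev  <- object@events
  if (!all(c("time", "code") %in% names(ev)))
    msg <- c(msg, "events need columns 'time' and 'code'")
  else if (nrow(ev) && (any(ev$time < 0) || any(ev$time > dur)))
    msg <- c(msg, "event times must lie within [0, duration]")
  if (length(msg)) msg else TRUE
})

#' Epoched EMG data locked to go-signal onset
#'
#' Trials x time amplitude matrix extracted around go-signal onsets, together
#' with the time axis (seconds relative to go onset), the sampling rate, the
#' processing-stage tag, per-trial metadata and per-trial rejection flags.
#' The stage tag advances only in the documented order
#' `filtered -> rms -> baseline_normalized -> zscored`.
#'
#' @slot data numeric matrix, trials x samples; each trial holds the channel
#'   of its required hand. Rejected trials keep their row (values may be NA).
#' @slot time numeric vector of sample times in s relative to go onset.
#' @slot rate sampling rate in Hz.
#' @slot stage one of `"filtered"`, `"rms"`, `"baseline_normalized"`,
#'   `"zscored"`.
#' @slot trials data.frame of per-trial metadata (trial_id, block, trial_type,
#'   ssd, rt, response_hand, required_hand, outcome, ...), one row per epoch.
#' @slot rejected character vector, `NA` for kept trials, otherwise the
#'   rejection reason (`"edge"`, `"baseline"`, `"flat baseline"`).
#' @slot baseline numeric length-2 vector: baseline window in s.
#'
#' @seealso [epochRecording()], [rmsEnvelope()], [baselineNormalize()],
#'   [zscoreByBlock()], [extractBursts()]
#' @export
setClass("EpochSet",
  representation(
    data     = "matrix",
    time     = "numeric",
    rate     = "numeric",
    stage    = "character",
    trials   = "data.frame",
    rejected = "character",
    baseline = "numeric"
  )
)

.EPOCH_STAGES <- c("filtered", "rms", "baseline_normalized", "zscored")

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (ncol(object@data) != length(object@time))
    msg <- c(msg, "time axis length must equal number of samples")
  if (length(object@time) > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0))
      msg <- c(msg, "time axis must be strictly increasing")
    if (max(abs(dt - 1 / object@rate)) > 1e-9)
      msg <- c(msg, "time step must equal 1/rate")
  }
  if (!(object@stage %in% .EPOCH_STAGES))
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(.EPOCH_STAGES, collapse = ", ")))
  if (nrow(object@trials) != nrow(object@data))
    msg <- c(msg, "one metadata row per epoch required")
  if (length(object@rejected) != nrow(object@data))
    msg <- c(msg, "one rejection flag per epoch required")
  if (length(object@baseline) != 2L || object@baseline[1] >= object@baseline[2])
    msg <- c(msg, "baseline must be an ordered length-2 window")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channel(s), %.1f s at %g Hz\n",
              nrow(object@samples), recordingDuration(object), object@rate))
  if (length(object@channels))
    cat("  channels:",
        paste(sprintf("%s(%s)", object@channels,
                      ifelse(object@channels %in% names(object@hands),
                             object@hands[object@channels], "?")),
              collapse = ", "), "\n")
  cat(sprintf("  events: %d marker(s)\n", nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d trial(s) x %d sample(s) at %g Hz [stage: %s]\n",
              nrow(object@data), ncol(object@data), object@rate,
              object@stage))
  nrej <- sum(!is.na(object@rejected))
  cat(sprintf("  window: [%.3f, %.3f] s; rejected: %d\n",
              min(object@time), max(object@time), nrej))
})
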