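#' Preprocessing configuration
#'
#' Numeric defaults of the EMG preprocessing chain: 20-250 Hz second-order
#' Butterworth bandpass, resampling to 500 Hz, epochs from -0.2 to 1.6 s
#' around go-signal onset, baseline window -0.2 to 0 s, rejection of epochs
#' with mean rectified baseline above 100 microvolts, and an RMS envelope
#' over a centered window of +/-5 samples.
#'
#' @param band numeric length-2, bandpass edges in Hz.
#' @param filter_order Butterworth order (per high/low section).
#' @param target_rate resampling target in Hz.
#' @param epoch_window numeric length-2, epoch window in s around go onset.
#' @param baseline_window numeric length-2, baseline window in s.
#' @param reject_baseline_uV rejection limit on mean rectified baseline
#'   amplitude, in microvolts.
#' @param rms_halfwidth half-width of the RMS window, in samples at
#'   `target_rate`.
#' @param zero_phase logical; `TRUE` applies the filter forward-backward
#'   (no group delay), `FALSE` causally.
#' @return a list of class `preprocess_config`.
#' @export
preprocessConfig <- function(band = c(20, 250), filter_order = 2,
                             target_rate = 500,
                             epoch_window = c(-0.2, 1.6),
                             baseline_window = c(-0.2, 0),
                             reject_baseline_uV = 100,
                             rms_halfwidth = 5,
                             zero_phase = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            band[2] <= target_rate / 2,
            filter_order >= 1, rms_halfwidth >= 0,
            epoch_window[1] < epoch_window[2],
            baseline_window[1] >= epoch_window[1],
            baseline_window[2] <= epoch_window[2])
  structure(list(band = band, filter_order = filter_order,
                 target_rate = target_rate, epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 reject_baseline_uV = reject_baseline_uV,
                 rms_halfwidth = rms_halfwidth, zero_phase = zero_phase),
            class = "preprocess_config")
}

#' Bandpass-filter a continuous recording
#'
#' Applies the configured Butterworth bandpass to every channel. With
#' `zero_phase = TRUE` (default) the filter runs forward and backward so
#' burst onset and peak latencies carry no group delay; causal filtering
#' would systematically delay them.
#'
#' @param recording a [ContinuousRecording-class].
#' @param config a [preprocessConfig()].
#' @return the filtered recording (same rate and length).
#' @export
bandpassFilter <- function(recording, config = preprocessConfig()) {
  rate <- recording@rate
  if (rate <= 2 * config$band[2])
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rate, config$band[2]), call. = FALSE)
  bf <- signal::butter(config$filter_order, config$band / (rate / 2),
                       type = "pass")
  apply_filter <- if (config$zero_phase)
    function(x) signal::filtfilt(bf, x)
  else
    function(x) as.numeric(signal::filter(bf, x))
  for (k in seq_len(nrow(recording@samples)))
    recording@samples[k, ] <- apply_filter(recording@samples[k, ])
  recording@meta$filtered <- list(band = config$band,
                                  order = config$filter_order,
                                  zero_phase = config$zero_phase)
  recording
}

#' Resample a recording to a lower rate
#'
#' Decimates to `target_rate` (every k-th sample for integer ratios, a
#' polyphase resampler otherwise). Meant to run after [bandpassFilter()],
#' whose upper band edge must not exceed the new Nyquist frequency. Event
#' times are kept in seconds and therefore unchanged.
#'
#' @param recording a [ContinuousRecording-class].
#' @param target_rate new rate in Hz (must not exceed the current rate).
#' @return the resampled recording.
#' @export
resampleRecording <- function(recording, target_rate = 500) {
  rate <- recording@rate
  if (target_rate > rate)
    stop("upsampling is not supported", call. = FALSE)
  if (target_rate == rate) return(recording)
  ratio <- rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(recording@samples), by = round(ratio))
    recording@samples <- recording@samples[, idx, drop = FALSE]
  } else {
    frac <- .simplifyRatio(target_rate, rate)
    recording@samples <- t(apply(recording@samples, 1, function(x)
      signal::resample(x, frac[1], frac[2])))
  }
  recording@rate <- target_rate
  recording@meta$resampled <- list(from = rate, to = target_rate)
  recording
}

.simplifyRatio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(p * 1e6), round(q * 1e6))
  c(round(p * 1e6) / d, round(q * 1e6) / d)
}

#' Extract go-locked epochs
#'
#' Cuts one epoch per trial from the channel of the trial's required hand,
#' over `epoch_window` (default -0.2 to 1.6 s) relative to go-signal onset.
#' The time axis contains a sample at exactly t = 0. Trials whose window
#' exceeds the recording bounds are flagged rejected with reason `"edge"`.
#'
#' @param recording a filtered (and typically resampled)
#'   [ContinuousRecording-class].
#' @param trials a validated trial table (see [validateTrialTable()]).
#' @param config a [preprocessConfig()].
#' @return an [EpochSet-class] at stage `"filtered"`.
#' @export
epochRecording <- function(recording, trials,
                           config = preprocessConfig()) {
  rate <- recording@rate
  w <- config$epoch_window
  nsamp <- round((w[2] - w[1]) * rate)
  time <- w[1] + (seq_len(nsamp) - 1L) / rate
  ntr <- nrow(trials)
  dat <- matrix(NA_real_, nrow = ntr, ncol = nsamp)
  rejected <- rep(NA_character_, ntr)
  nrec <- ncol(recording@samples)
  for (i in seq_len(ntr)) {
    chan <- .handChannel(recording, trials$required_hand[i])
    start <- round((trials$go_onset[i] + w[1]) * rate) + 1L
    idx <- start:(start + nsamp - 1L)
    if (start < 1L || idx[nsamp] > nrec) {
      rejected[i] <- "edge"
      next
    }
    dat[i, ] <- chan[idx]
  }
  meta <- trials
  meta$hand <- trials$required_hand
  new("EpochSet", data = dat, time = time, rate = rate,
      stage = "filtered", trials = meta, rejected = rejected,
      baseline = config$baseline_window)
}

.baselineCols <- function(epochs) {
  which(epochs@time >= epochs@baseline[1] - 1e-12 &
        epochs@time <  epochs@baseline[2] - 1e-12)
}

#' Reject epochs with high baseline activity
#'
#' Flags trials whose mean rectified amplitude over the baseline window
#' exceeds the limit (default 100 microvolts) as rejected with reason
#' `"baseline"`. Runs on the filtered signal, before envelope computation.
#'
#' @param epochs an [EpochSet-class] at stage `"filtered"`.
#' @param limit_uV rejection limit in microvolts.
#' @return the epoch set with updated rejection flags.
#' @export
rejectHighBaseline <- function(epochs, limit_uV = 100) {
  if (epochs@stage != "filtered")
    stop("baseline rejection runs on the filtered signal", call. = FALSE)
  cols <- .baselineCols(epochs)
  keep <- is.na(epochs@rejected)
  bl <- rowMeans(abs(epochs@data[, cols, drop = FALSE]))
  hit <- keep & !is.na(bl) & bl > limit_uV
  epochs@rejected[hit] <- "baseline"
  message(sprintf("baseline rejection: %d of %d trials (%.2f%%) above %g uV",
                  sum(hit), sum(keep), 100 * sum(hit) / max(1, sum(keep)),
                  limit_uV))
  epochs
}

#' Root-mean-square envelope
#'
#' Replaces each sample by the RMS over a centered window of
#' `2 * halfwidth + 1` samples (default +/-5 samples, ~22 ms at 500 Hz).
#' At epoch borders the window shrinks rather than padding with fabricated
#' data. Output is non-negative; stage advances to `"rms"`.
#'
#' @param epochs an [EpochSet-class] at stage `"filtered"`.
#' @param halfwidth half window width in samples.
#' @return the epoch set at stage `"rms"`.
#' @export
rmsEnvelope <- function(epochs, halfwidth = 5) {
  n <- ncol(epochs@data)
  if (halfwidth >= n)
    stop("halfwidth must be smaller than the epoch length", call. = FALSE)
  epochs <- .advanceStage(epochs, "filtered", "rms")
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  len <- hi - lo + 1
  for (r in which(is.na(epochs@rejected))) {
    cs <- cumsum(c(0, epochs@data[r, ]^2))
    epochs@data[r, ] <- sqrt((cs[hi + 1L] - cs[lo]) / len)
  }
  epochs
}

#' Baseline-normalize envelopes
#'
#' Divides every trial's full time-course by that trial's mean envelope over
#' the baseline window, so the normalized baseline mean is 1. Trials with a
#' zero baseline mean are rejected with reason `"flat baseline"`.
#'
#' @param epochs an [EpochSet-class] at stage `"rms"`.
#' @return the epoch set at stage `"baseline_normalized"`.
#' @export
baselineNormalize <- function(epochs) {
  epochs <- .advanceStage(epochs, "rms", "baseline_normalized")
  cols <- .baselineCols(epochs)
  for (r in which(is.na(epochs@rejected))) {
    m <- mean(epochs@data[r, cols])
    if (!is.finite(m) || m == 0) {
      epochs@rejected[r] <- "flat baseline"
      next
    }
    epochs@data[r, ] <- epochs@data[r, ] / m
  }
  epochs
}

#' Z-score epochs block-wise
#'
#' For each (hand, block) group, concatenates all kept epochs into one
#' vector, computes its grand mean and population standard deviation
#' (divisor N), and transforms every sample to (x - mean) / sd. After the
#' transform each concatenated group has mean 0 and sd 1 exactly.
#'
#' @param epochs an [EpochSet-class] at stage `"baseline_normalized"`.
#' @return the epoch set at stage `"zscored"`.
#' @export
zscoreByBlock <- function(epochs) {
  epochs <- .advanceStage(epochs, "baseline_normalized", "zscored")
  keep <- which(is.na(epochs@rejected))
  groups <- split(keep,
                  paste(epochs@trials$hand[keep], epochs@trials$block[keep]))
  for (rows in groups) {
    v <- as.numeric(epochs@data[rows, , drop = FALSE])
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s == 0)
      stop("zero variance in a (hand, block) group", call. = FALSE)
    epochs@data[rows, ] <- (epochs@data[rows, , drop = FALSE] - m) / s
  }
  epochs
}

#' Run the full preprocessing chain
#'
#' Bandpass filter at the native rate, resample, epoch, reject high-baseline
#' trials, RMS envelope, baseline normalization, and block-wise z-scoring —
#' the documented stage order.
#'
#' @param recording a raw [ContinuousRecording-class].
#' @param trials a validated trial table.
#' @param config a [preprocessConfig()].
#' @return an [EpochSet-class] at stage `"zscored"`.
#' @export
preprocessEmg <- function(recording, trials, config = preprocessConfig()) {
  recording <- bandpassFilter(recording, config)
  recording <- resampleRecording(recording, config$target_rate)
  epochs <- epochRecording(recording, trials, config)
  epochs <- rejectHighBaseline(epochs, config$reject_baseline_uV)
  epochs <- rmsEnvelope(epochs, config$rms_halfwidth)
  epochs <- baselineNormalize(epochs)
  zscoreByBlock(epochs)
}
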