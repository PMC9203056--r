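# Independent brute-force oracles. These deliberately use naive loops and
# never call the package's detection/envelope code paths.

# O(n) exhaustive scan for the maximum within the search window
oracleDetect <- function(trace, time, threshold = 1.2,
                         window = c(0, 1.6)) {
  idx <- which(time >= window[1] - 1e-12 & time <= window[2] + 1e-12)
  best <- NA_integer_; bestv <- -Inf; hit <- FALSE
  for (i in idx) {
    v <- trace[i]
    if (is.na(v)) next
    if (v > threshold) hit <- TRUE
    if (v > bestv) { bestv <- v; best <- i }
  }
  list(detected = hit,
       peak_index = if (hit) best else NA_integer_,
       peak_amp = if (hit) bestv else NA_real_)
}

# naive backward run search for the burst onset
oracleOnset <- function(trace, time, peak_index, rate, threshold = 1.2,
                        onset_run_ms = 8, window = c(0, 1.6)) {
  idx <- which(time >= window[1] - 1e-12 & time <= window[2] + 1e-12)
  first <- idx[1]
  n_run <- max(1L, as.integer(round(onset_run_ms / 1000 * rate)))
  i <- as.integer(peak_index) - 1L
  while (i >= first) {
    all_below <- TRUE
    if (i - n_run + 1L < first) break
    for (j in i:(i - n_run + 1L)) {
      if (is.na(trace[j]) || trace[j] >= threshold) { all_below <- FALSE; break }
    }
    if (all_below) return(list(onset_index = i + 1L, warn = FALSE))
    i <- i - 1L
  }
  list(onset_index = first, warn = TRUE)
}

# O(n * w) per-sample RMS with truncated edge windows
oracleRms <- function(x, halfwidth) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - halfwidth)
    hi <- min(n, i + halfwidth)
    out[i] <- sqrt(mean(x[lo:hi]^2))
  }
  out
}

# expected split-half (Spearman-Brown corrected) reliability of the mean of
# n trials with between-subject sd b and within-subject sd w:
# half-split reliability r = b^2 / (b^2 + w^2/(n/2) ...), here derived from
# the half sizes used by the package (floor/ceiling)
oracleIccReliability <- function(b, w, n) {
  n1 <- floor(n / 2); n2 <- ceiling(n / 2)
  r <- b^2 / sqrt((b^2 + w^2 / n1) * (b^2 + w^2 / n2))
  2 * r / (1 + r)
}

# build a minimal z-scored EpochSet directly from a trials x time matrix
makeEpochSet <- function(data, rate = 500, t0 = -0.2,
                         stage = "zscored", trials = NULL,
                         baseline = c(-0.2, 0)) {
  n <- ncol(data)
  time <- t0 + (seq_len(n) - 1) / rate
  if (is.null(trials))
    trials <- data.frame(
      trial_id = sprintf("t%03d", seq_len(nrow(data))),
      block = 1L, trial_type = "go", go_onset = seq_len(nrow(data)) * 3,
      ssd = NA_real_, response_hand = "right", rt = 500,
      required_hand = "right",
      outcome = "go_correct", hand = "right")
  new("EpochSet", data = data, time = time, rate = rate, stage = stage,
      trials = trials, rejected = rep(NA_character_, nrow(data)),
      baseline = baseline)
}
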