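#' Stop-signal-task simulation configuration
#'
#' Defaults parameterize an independent horse race over a standard
#' stop-signal design: 46 participants, 684 go and 216 stop trials (24%
#' stop) in 6 blocks, go finishing times with mean 546 ms and within-subject
#' sd 114 ms (participant means jittered with sd 77 ms), stop latencies with
#' mean 202 ms and within-subject sd 31 ms (between-subject sd 21 ms), go
#' failures at 1.6% and trigger failures at 1.3%, a 1-up-1-down SSD
#' staircase starting at 250 ms with 50 ms steps clamped to 100-800 ms, a
#' 1000 ms response window, and motor times (RT minus EMG onset) with mean
#' 57 ms and sd 13 ms.
#'
#' @param n_participants,n_go,n_stop,n_blocks design sizes.
#' @param go_mean,go_sd go finishing-time distribution (ms, within subject).
#' @param stop_mean,stop_sd stop-latency distribution (ms, within subject).
#' @param between_go_sd,between_stop_sd between-subject sd of the means (ms).
#' @param p_go_failure,p_trigger_failure,p_choice_error failure/choice-error
#'   probabilities per trial.
#' @param staircase_init,staircase_step,staircase_min,staircase_max SSD
#'   staircase parameters (ms).
#' @param motor_time_mean,motor_time_sd motor-time distribution (ms).
#' @param response_window maximum collected RT (ms).
#' @param dependence `"independent"` (stable stop latency) or
#'   `"onset_coupled"` (peripheral stop latency positively coupled to EMG
#'   onset at the single-trial level).
#' @param coupling coupling coefficient (ms of peripheral stop latency per
#'   ms of onset deviation) used when `dependence = "onset_coupled"`.
#' @param seed global seed; expands deterministically into per-participant
#'   streams.
#' @return a list of class `sim_config`.
#' @export
simConfig <- function(n_participants = 46, n_go = 684, n_stop = 216,
                      n_blocks = 6,
                      go_mean = 546, go_sd = 114,
                      stop_mean = 202, stop_sd = 31,
                      between_go_sd = 77, between_stop_sd = 21,
                      p_go_failure = 0.016, p_trigger_failure = 0.013,
                      p_choice_error = 0.007,
                      staircase_init = 250, staircase_step = 50,
                      staircase_min = 100, staircase_max = 800,
                      motor_time_mean = 57, motor_time_sd = 13,
                      response_window = 1000,
                      dependence = c("independent", "onset_coupled"),
                      coupling = 0.5, seed = 1) {
  dependence <- match.arg(dependence)
  stopifnot(go_mean > 0, go_sd > 0, stop_mean > 0, stop_sd > 0,
            p_go_failure >= 0, p_go_failure <= 1,
            p_trigger_failure >= 0, p_trigger_failure <= 1,
            staircase_min <= staircase_init,
            staircase_init <= staircase_max)
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic-EMG configuration
#'
#' Shape of the synthesized thumb-muscle EMG: a band-limited noise floor
#' plus, for every initiated response, a burst whose envelope rises linearly
#' from the EMG onset to a peak and then decays. In successful stop trials
#' whose muscle activity started before the peripheral stop latency elapsed,
#' a truncated burst (prEMG) is placed with its peak at
#' SSD + peripheral stop latency and an amplitude scaled by the accumulation
#' time, capped below the full-burst amplitude.
#'
#' @param rate sampling rate in Hz (5000 emulates BrainAmp acquisition;
#'   lower rates make desk-scale cohorts cheap).
#' @param noise_sd noise-floor sd in microvolts.
#' @param burst_amp full-burst carrier sd at the peak, in microvolts.
#' @param burst_rise,burst_fall envelope rise and decay times in ms.
#' @param rise_shape exponent of the rising flank
#'   (`((t - onset) / rise)^shape`); values below 1 give the steep initial
#'   recruitment seen in real bursts, so the detection threshold is crossed
#'   within a few ms of true activation.
#' @param premg_trunc_mean,premg_trunc_sd peripheral stop-latency
#'   distribution (ms after the stop signal) at which prEMG is truncated.
#' @param premg_amp_cap cap on the prEMG amplitude as a fraction of the
#'   full-burst amplitude.
#' @param carrier_band bandpass of noise floor and burst carrier, Hz.
#' @param p_noisy_baseline fraction of trials with an injected
#'   high-amplitude noisy baseline (for rejection-rate checks).
#' @param noisy_baseline_uV sd of the injected baseline noise.
#' @return a list of class `emg_config`.
#' @export
emgConfig <- function(rate = 5000, noise_sd = 2, burst_amp = 25,
                      burst_rise = 52, burst_fall = 60, rise_shape = 0.4,
                      premg_trunc_mean = 165, premg_trunc_sd = 25,
                      premg_amp_cap = 0.8,
                      carrier_band = c(20, 250),
                      p_noisy_baseline = 0, noisy_baseline_uV = 250) {
  stopifnot(burst_amp > noise_sd, burst_rise > 0, burst_fall > 0,
            premg_amp_cap > 0, premg_amp_cap < 1)
  structure(as.list(environment()), class = "emg_config")
}

#' One staircase update
#'
#' 1-up-1-down tracking: the SSD increases by one step after a successful
#' stop and decreases by one step after an unsuccessful stop, clamped to
#' the configured bounds.
#'
#' @param ssd current SSD in ms.
#' @param success logical, was the stop successful (no response)?
#' @param step step size in ms.
#' @param lo,hi clamp bounds in ms.
#' @return updated SSD.
#' @export
staircaseUpdate <- function(ssd, success, step = 50, lo = 100, hi = 800) {
  min(hi, max(lo, ssd + if (success) step else -step))
}

.participantSeeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_participants)
}

#' Simulate stop-signal-task behaviour
#'
#' Independent-race simulation with staircase SSD tracking for a whole
#' cohort. Per trial, go and stop finishing times are drawn from the
#' configured (participant-jittered) distributions; a stop trial produces a
#' response iff the go process was initiated and either the stop process was
#' never triggered or the go process finished before SSD + stop latency.
#' Go failures yield omissions; responses beyond the response window are
#' omissions too. The staircase advances in presentation order; blocks and
#' alternating response hands follow the task design.
#'
#' @param config a [simConfig()].
#' @return list with `trials` (validated trial table with a `participant`
#'   column and per-participant recording-clock onsets) and `truth`
#'   (per-trial ground truth: finishing times, failure flags).
#' @export
simulateBehavior <- function(config = simConfig()) {
  seeds <- .participantSeeds(config)
  all_tr <- vector("list", config$n_participants)
  all_gt <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    set.seed(seeds[p])
    res <- .simulateParticipant(config, p)
    all_tr[[p]] <- res$trials
    all_gt[[p]] <- res$truth
  }
  list(trials = do.call(rbind, all_tr), truth = do.call(rbind, all_gt))
}

.simulateParticipant <- function(config, p) {
  n <- config$n_go + config$n_stop
  go_mu <- config$go_mean + stats::rnorm(1, 0, config$between_go_sd)
  stop_mu <- config$stop_mean + stats::rnorm(1, 0, config$between_stop_sd)

  # stop positions randomized, but the run-in stays go-only
  run_in <- min(10L, n - config$n_stop)
  is_stop <- rep(FALSE, n)
  is_stop[sample((run_in + 1L):n, config$n_stop)] <- TRUE

  block <- sort(rep(seq_len(config$n_blocks), length.out = n))
  hand <- rep(c("left", "right"), length.out = n)
  onset <- 2 + cumsum(c(0, stats::runif(n - 1, 2.4, 2.9)))

  G <- pmax(100, stats::rnorm(n, go_mu, config$go_sd))
  S <- pmax(50, stats::rnorm(n, stop_mu, config$stop_sd))
  go_fail <- stats::runif(n) < config$p_go_failure
  trig_fail <- stats::runif(n) < config$p_trigger_failure
  choice_err <- stats::runif(n) < config$p_choice_error

  ssd <- rep(NA_real_, n)
  responded <- logical(n)
  cur <- config$staircase_init
  for (i in seq_len(n)) {
    if (is_stop[i]) {
      ssd[i] <- cur
      responded[i] <- !go_fail[i] && G[i] <= config$response_window &&
        (trig_fail[i] || G[i] < cur + S[i])
      cur <- staircaseUpdate(cur, !responded[i], config$staircase_step,
                             config$staircase_min, config$staircase_max)
    } else {
      responded[i] <- !go_fail[i] && G[i] <= config$response_window
    }
  }
  resp_hand <- ifelse(!responded, "none",
                      ifelse(choice_err,
                             ifelse(hand == "left", "right", "left"),
                             hand))
  rt <- ifelse(responded, G, NA_real_)

  trials <- validateTrialTable(data.frame(
    trial_id = sprintf("p%02d_t%04d", p, seq_len(n)),
    block = block,
    trial_type = ifelse(is_stop, "stop", "go"),
    go_onset = onset,
    ssd = ssd,
    response_hand = resp_hand,
    rt = rt,
    required_hand = hand), config$response_window)
  trials <- cbind(participant = p, trials)

  truth <- data.frame(
    participant = p, trial_id = trials$trial_id,
    go_finish = G, stop_finish = ifelse(is_stop, S, NA_real_),
    go_fail = go_fail, trig_fail = ifelse(is_stop, trig_fail, NA),
    go_mu = go_mu, stop_mu = stop_mu)
  list(trials = trials, truth = truth)
}

# unit-variance band-limited noise
.bandNoise <- function(n, rate, band) {
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Synthesize continuous EMG for one simulated participant
#'
#' Builds a two-channel (left/right hand) continuous recording: a
#' band-limited noise floor plus one burst per initiated response. Full
#' bursts rise from the true EMG onset (RT minus a motor-time draw) to a
#' peak and decay; successful stop trials whose muscle activity started
#' before SSD + peripheral stop latency receive a truncated prEMG burst with
#' its peak at that time and amplitude proportional to accumulation time.
#' Ground truth is updated with the exact onset/peak times.
#'
#' @param trials one participant's trial table (from [simulateBehavior()]).
#' @param truth matching ground-truth rows.
#' @param emg a [emgConfig()].
#' @param config the [simConfig()] used for behaviour (motor-time and
#'   coupling parameters).
#' @param seed RNG seed for the EMG stream.
#' @return list with `recording` ([ContinuousRecording-class]) and `truth`
#'   extended with `true_onset`, `true_peak`, `true_peak_stop`,
#'   `true_amp`, `premg_true`, `motor_draw`.
#' @export
synthesizeEmg <- function(trials, truth, emg = emgConfig(),
                          config = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- emg$rate
  n <- nrow(trials)
  dur <- max(trials$go_onset) + 2
  nsamp <- ceiling(dur * rate)
  chans <- c("EMG_left", "EMG_right")
  samples <- rbind(.bandNoise(nsamp, rate, emg$carrier_band),
                   .bandNoise(nsamp, rate, emg$carrier_band)) * emg$noise_sd
  rownames(samples) <- chans

  motor <- pmax(20, stats::rnorm(n, config$motor_time_mean,
                                 config$motor_time_sd))
  amp <- emg$burst_amp * exp(stats::rnorm(n, 0, 0.15))
  peri <- stats::rnorm(n, emg$premg_trunc_mean, emg$premg_trunc_sd)

  truth$true_onset <- NA_real_; truth$true_peak <- NA_real_
  truth$true_peak_stop <- NA_real_; truth$true_amp <- NA_real_
  truth$premg_true <- FALSE; truth$motor_draw <- motor

  noisy_bl <- stats::runif(n) < emg$p_noisy_baseline
  ch_idx <- ifelse(trials$required_hand == "left", 1L, 2L)

  for (i in seq_len(n)) {
    onset_ms <- peak_ms <- NA_real_; a <- NA_real_; fall <- emg$burst_fall
    if (!is.na(trials$rt[i])) {                       # full response burst
      onset_ms <- truth$go_finish[i] - motor[i]
      peak_ms <- onset_ms + emg$burst_rise
      a <- amp[i]
    } else if (trials$outcome[i] == "stop_success" && !truth$go_fail[i]) {
      cand <- truth$go_finish[i] - motor[i]           # would-be EMG onset
      peri_i <- peri[i]
      if (config$dependence == "onset_coupled")
        peri_i <- peri_i + config$coupling *
          (cand - trials$ssd[i] - (config$go_mean - config$motor_time_mean -
                                   trials$ssd[i]))
      cut_ms <- trials$ssd[i] + peri_i
      if (cand < cut_ms) {                            # truncated prEMG burst
        onset_ms <- cand
        peak_ms <- cut_ms
        acc <- peak_ms - onset_ms
        a <- amp[i] * min(emg$premg_amp_cap, sqrt(acc / emg$burst_rise))
        fall <- emg$burst_fall / 2
        truth$premg_true[i] <- TRUE
        truth$true_peak_stop[i] <- peak_ms - trials$ssd[i]
      }
    }
    if (!is.na(onset_ms)) {
      truth$true_onset[i] <- onset_ms
      truth$true_peak[i] <- peak_ms
      truth$true_amp[i] <- a
      if (!is.na(trials$rt[i]) && trials$trial_type[i] == "stop")
        truth$true_peak_stop[i] <- peak_ms - trials$ssd[i]
      t0 <- trials$go_onset[i] + onset_ms / 1000
      tp <- trials$go_onset[i] + peak_ms / 1000
      tend <- min(tp + 5 * fall / 1000, dur,
                  if (i < n) trials$go_onset[i + 1] else dur)
      j0 <- max(1L, round(t0 * rate)); j1 <- min(nsamp, round(tend * rate))
      if (j1 > j0) {
        tt <- (j0:j1) / rate
        env <- ifelse(tt <= tp,
                      pmax((tt - t0) / max(tp - t0, 1e-6), 0)^emg$rise_shape,
                      exp(-(tt - tp) / (fall / 1000)))
        env <- env * a
        carrier <- .bandNoise(j1 - j0 + 1L, rate, emg$carrier_band)
        samples[ch_idx[i], j0:j1] <-
          samples[ch_idx[i], j0:j1] + env * carrier
      }
    }
    if (noisy_bl[i]) {                                # contaminated baseline
      b0 <- max(1L, round((trials$go_onset[i] - 0.25) * rate))
      b1 <- min(nsamp, round(trials$go_onset[i] * rate))
      samples[ch_idx[i], b0:b1] <- samples[ch_idx[i], b0:b1] +
        .bandNoise(b1 - b0 + 1L, rate, emg$carrier_band) *
          emg$noisy_baseline_uV
    }
  }
  truth$noisy_baseline <- noisy_bl

  is_stop <- trials$trial_type == "stop"
  events <- rbind(
    data.frame(time = trials$go_onset, code = "go"),
    data.frame(time = trials$go_onset[is_stop] +
                 trials$ssd[is_stop] / 1000, code = "stop"))
  events <- events[order(events$time), ]

  rec <- new("ContinuousRecording", samples = samples, rate = rate,
             channels = chans,
             hands = c(EMG_left = "left", EMG_right = "right"),
             events = events,
             meta = list(source = "synthesized", participant =
                           trials$participant[1]))
  list(recording = rec, truth = truth)
}

#' Simulate a full cohort with EMG
#'
#' Behaviour plus synthesized EMG for every participant, with
#' per-participant RNG streams derived from the global seed.
#'
#' @param config a [simConfig()].
#' @param emg an [emgConfig()].
#' @return list with `trials`, `truth` and `recordings` (one
#'   [ContinuousRecording-class] per participant).
#' @export
simulateCohort <- function(config = simConfig(), emg = emgConfig()) {
  beh <- simulateBehavior(config)
  seeds <- .participantSeeds(config)
  recs <- vector("list", config$n_participants)
  gts <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    tr <- beh$trials[beh$trials$participant == p, ]
    gt <- beh$truth[beh$truth$participant == p, ]
    res <- synthesizeEmg(tr, gt, emg, config,
                         seed = (seeds[p] + 7L) %% .Machine$integer.max)
    recs[[p]] <- res$recording
    gts[[p]] <- res$truth
  }
  list(trials = beh$trials, truth = do.call(rbind, gts),
       recordings = recs)
}

#' Write a simulated fixture to disk
#'
#' Writes per-participant recordings (BrainVision triplet or delimited text
#' + sidecar), a tab-separated trial table with a `participant` column, and
#' the ground-truth CSV. Deterministic given the config seed.
#'
#' @param config a [simConfig()].
#' @param emg an [emgConfig()].
#' @param out_dir output directory (created if needed).
#' @param format `"brainvision"` or `"delimited"`.
#' @return list of written paths, invisibly.
#' @export
makeFixture <- function(config = simConfig(), emg = emgConfig(),
                        out_dir, format = c("brainvision", "delimited")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCohort(config, emg)
  rec_paths <- character(config$n_participants)
  for (p in seq_len(config$n_participants)) {
    stem <- file.path(out_dir, sprintf("sub-%02d_emg", p))
    rec_paths[p] <- if (format == "brainvision")
      writeBrainVision(sim$recordings[[p]], stem)
    else
      writeDelimitedRecording(sim$recordings[[p]], paste0(stem, ".tsv"))
  }
  trials_path <- file.path(out_dir, "trials.tsv")
  writeTrialTable(sim$trials, trials_path)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE, na = "")
  invisible(list(recordings = rec_paths, trials = trials_path,
                 truth = truth_path))
}
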