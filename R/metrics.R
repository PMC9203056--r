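# Behavioural and EMG summary metrics. All latencies are in ms; percentages
# in [0, 100]. Where a data frame carries a `participant` column the
# computation is done per participant; otherwise it is treated as a single
# participant's data.

.withParticipant <- function(df) {
  if (!"participant" %in% names(df)) df$participant <- 1L
  df
}

# mean of per-hand means: asymmetric trial counts must not silently reweight
.handMean <- function(values, hands) {
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  mean(tapply(values[ok], hands[ok], mean))
}

# modal SSD; ties broken toward the lowest SSD
.modalSsd <- function(ssd) {
  tab <- table(ssd)
  as.numeric(names(tab)[which.max(tab)])
}

#' Behavioural summary of a trial table
#'
#' Go accuracy / error / omission percentages, mean go RT (correct responses
#' only), mean unsuccessful-stop RT, mean SSD over stop trials and stop
#' accuracy, for one participant.
#'
#' @param trials a validated trial table (see [validateTrialTable()]).
#' @return a one-row data.frame.
#' @export
behavioralSummary <- function(trials) {
  go <- trials[trials$trial_type == "go", ]
  st <- trials[trials$trial_type == "stop", ]
  if (!nrow(st)) stop("no stop trials", call. = FALSE)
  data.frame(
    n_go = nrow(go), n_stop = nrow(st),
    go_accuracy_pct = 100 * mean(go$outcome == "go_correct"),
    go_error_pct    = 100 * mean(go$outcome == "go_error"),
    go_omission_pct = 100 * mean(go$outcome == "go_omission"),
    go_rt = mean(go$rt[go$outcome == "go_correct"]),
    usstop_rt = mean(st$rt[st$outcome == "stop_fail"]),
    mean_ssd = mean(st$ssd),
    stop_accuracy_pct = 100 * mean(st$outcome == "stop_success"))
}

#' Integration-method SSRT
#'
#' Builds the go-RT distribution from all go trials — choice-error RTs are
#' included and each omission is replaced by the participant's maximum go RT
#' — takes its `ceiling(p * n)`-th ascending value at
#' p = P(response | stop), and subtracts the mean SSD. Undefined (flagged)
#' when p is 0 or 1.
#'
#' @param trials a validated trial table.
#' @return list with `ssrt` (ms, `NA` when undefined), `p_respond`,
#'   `nth_rt`, `mean_ssd` and logical `undefined`.
#' @export
ssrtIntegration <- function(trials) {
  go <- trials[trials$trial_type == "go", ]
  st <- trials[trials$trial_type == "stop", ]
  if (!nrow(st) || !any(!is.na(go$rt)))
    stop("need at least one stop trial and one go response", call. = FALSE)
  goRT <- go$rt
  goRT[is.na(goRT)] <- max(goRT, na.rm = TRUE)  # omission replacement
  p <- mean(st$outcome == "stop_fail")
  if (p <= 0 || p >= 1)
    return(list(ssrt = NA_real_, p_respond = p, nth_rt = NA_real_,
                mean_ssd = mean(st$ssd), undefined = TRUE))
  nth <- sort(goRT)[ceiling(p * length(goRT))]
  list(ssrt = nth - mean(st$ssd), p_respond = p, nth_rt = nth,
       mean_ssd = mean(st$ssd), undefined = FALSE)
}

#' prEMG peak latency, three estimators
#'
#' Stop-locked prEMG peak latency for one participant by one of three
#' methods: `single_trial` averages the per-trial stop-locked peaks over all
#' prEMG trials; `average_waveform` stop-locks every prEMG envelope, averages
#' them point-wise and takes the peak of the mean waveform;
#' `mode_ssd` averages per-trial peaks over prEMG trials at the participant's
#' modal SSD (ties toward the lowest SSD).
#'
#' @param bursts burst table from [extractBursts()].
#' @param epochs the z-scored [EpochSet-class] the bursts came from
#'   (required for `average_waveform`).
#' @param method one of `"single_trial"`, `"average_waveform"`,
#'   `"mode_ssd"`.
#' @return latency in ms, or `NA` when no prEMG trial is available.
#' @export
premgPeakLatency <- function(bursts, epochs = NULL,
                             method = c("single_trial", "average_waveform",
                                        "mode_ssd")) {
  method <- match.arg(method)
  pr <- bursts[bursts$emg_class == "premg", ]
  if (!nrow(pr)) return(NA_real_)
  if (method == "single_trial")
    return(mean(pr$peak_stop))
  if (method == "mode_ssd") {
    ssd0 <- .modalSsd(bursts$ssd[bursts$trial_type == "stop"])
    at <- pr$peak_stop[pr$ssd == ssd0]
    return(if (length(at)) mean(at) else NA_real_)
  }
  # average_waveform: stop-lock each prEMG envelope, point-wise mean, peak
  if (is.null(epochs))
    stop("average_waveform needs the epochs", call. = FALSE)
  rate <- epochs@rate
  time <- epochs@time
  rows <- match(pr$trial_id, epochs@trials$trial_id)
  n <- length(time)
  shifted <- matrix(NA_real_, nrow = nrow(pr), ncol = n)
  for (i in seq_len(nrow(pr))) {
    sh <- round(pr$ssd[i] / 1000 * rate)
    src <- (1 + sh):n
    shifted[i, seq_along(src)] <- epochs@data[rows[i], src]
  }
  cover <- colSums(!is.na(shifted))
  avg <- colMeans(shifted, na.rm = TRUE)
  post <- which(time >= 0 & cover >= max(1, ceiling(nrow(pr) / 2)))
  if (!length(post)) return(NA_real_)
  time[post[which.max(avg[post])]] * 1000
}

#' Behaviour- and EMG-based inhibition functions
#'
#' For each participant, centers the SSDs on the modal SSD (ties toward the
#' lowest) in staircase-step units and, at each step from -3 to +3, computes
#' p(button press | stop) and p(EMG | stop). The EMG numerator is the count
#' of unsuccessful stop trials plus successful stop trials with prEMG, so
#' p(EMG|stop) >= p(press|stop) holds by construction at every step.
#'
#' @param bursts burst table (optionally with a `participant` column).
#' @param step staircase step in ms (default 50).
#' @return list with `per_participant` (participant, step, n, p_press,
#'   p_emg) and `group` (step-wise means across participants).
#' @export
inhibitionFunctions <- function(bursts, step = 50) {
  bursts <- .withParticipant(bursts)
  st <- bursts[bursts$trial_type == "stop", ]
  per <- do.call(rbind, lapply(split(st, st$participant), function(d) {
    ctr <- (d$ssd - .modalSsd(d$ssd)) / step
    keep <- abs(ctr) <= 3
    d <- d[keep, ]; ctr <- ctr[keep]
    agg <- lapply(split(seq_len(nrow(d)), ctr), function(i) {
      data.frame(n = length(i),
                 p_press = mean(d$outcome[i] == "stop_fail"),
                 p_emg = mean(d$outcome[i] == "stop_fail" |
                              d$emg_class[i] == "premg"))
    })
    cbind(participant = d$participant[1],
          step = as.numeric(names(agg)), do.call(rbind, agg))
  }))
  rownames(per) <- NULL
  grp <- do.call(rbind, lapply(split(per, per$step), function(d)
    data.frame(step = d$step[1], n_participants = nrow(d),
               p_press = mean(d$p_press), p_emg = mean(d$p_emg))))
  rownames(grp) <- NULL
  list(per_participant = per, group = grp)
}

#' Partition the go distribution by stop-trial probabilities
#'
#' Context-independence check: sorts the go distribution (go RTs, or
#' go-trial EMG onsets) and splits it at the percentiles corresponding to
#' p(press|stop) and p(EMG|stop). The left portion (fast) should match
#' unsuccessful-stop trials under the horse-race model, the middle portion
#' should match prEMG trials, and the right portion (slow) should be slower
#' than prEMG. Portions tile the distribution exactly
#' (`k1 = ceiling(p_press * n)`, `k2 = ceiling(p_emg * n)`).
#'
#' With `n_subsamples > 0`, go subsets size-matched to the comparison trial
#' counts are redrawn from the fast and middle portions and the fraction of
#' draws preserving each ordering is reported.
#'
#' @param trials validated trial table for one participant.
#' @param bursts matching burst table.
#' @param level `"rt"` (button-press RTs) or `"emg_onset"` (go-EMG onset
#'   latencies).
#' @param n_subsamples number of size-matched redraws (0 = none).
#' @return list with `p_press`, `p_emg`, `portions` (portion, n, mean,
#'   median), `comparison` (comparison trial means) and `subsample`
#'   (ordering-preservation fractions, or `NULL`).
#' @export
partitionGoDistribution <- function(trials, bursts,
                                    level = c("rt", "emg_onset"),
                                    n_subsamples = 0) {
  level <- match.arg(level)
  st <- trials[trials$trial_type == "stop", ]
  if (!nrow(st)) stop("no stop trials", call. = FALSE)
  stb <- bursts[bursts$trial_type == "stop", ]
  p_press <- mean(st$outcome == "stop_fail")
  p_emg <- (sum(stb$outcome == "stop_fail") +
            sum(stb$emg_class == "premg")) / nrow(stb)

  if (level == "rt") {
    values <- trials$rt[trials$trial_type == "go" & !is.na(trials$rt)]
    comparison <- data.frame(
      name = "usstop_rt",
      mean = mean(st$rt[st$outcome == "stop_fail"], na.rm = TRUE))
    n_fast_cmp <- sum(st$outcome == "stop_fail")
    med_cmp <- NA_real_; n_med_cmp <- 0L
  } else {
    goe <- bursts[bursts$emg_class == "go_emg", ]
    values <- goe$onset_go
    us <- bursts$onset_go[bursts$emg_class == "ustop_emg"]
    pr <- bursts$onset_go[bursts$emg_class == "premg"]
    comparison <- data.frame(
      name = c("usstop_emg_onset", "premg_onset"),
      mean = c(mean(us), if (length(pr)) mean(pr) else NA_real_))
    n_fast_cmp <- length(us)
    med_cmp <- if (length(pr)) mean(pr) else NA_real_
    n_med_cmp <- length(pr)
  }
  values <- sort(values)
  n <- length(values)
  if (!n) stop("empty go distribution", call. = FALSE)
  k1 <- min(n, ceiling(p_press * n))
  k2 <- min(n, max(k1, ceiling(p_emg * n)))
  idx <- list(fast = seq_len(k1),
              medium = if (k2 > k1) (k1 + 1):k2 else integer(0),
              slow = if (n > k2) (k2 + 1):n else integer(0))
  portions <- do.call(rbind, lapply(names(idx), function(nm) {
    v <- values[idx[[nm]]]
    data.frame(portion = nm, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  }))

  subsample <- NULL
  if (n_subsamples > 0) {
    fast_v <- values[idx$fast]; med_v <- values[idx$medium]
    ok_fast <- n_fast_cmp > 0 && length(fast_v) > 0
    ok_med <- n_med_cmp > 0 && length(med_v) > 0
    cmp_fast <- comparison$mean[1]
    draws <- vapply(seq_len(n_subsamples), function(i) {
      f <- if (ok_fast)
        mean(sample(fast_v, min(n_fast_cmp, length(fast_v)))) else NA_real_
      m <- if (ok_med)
        mean(sample(med_v, min(n_med_cmp, length(med_v)))) else NA_real_
      c(fast_le_cmp = !is.na(f) && f <= cmp_fast,
        cmp_med_ge_pr = !is.na(m) && !is.na(med_cmp) && m >= med_cmp,
        fast_lt_med = !is.na(f) && !is.na(m) && f < m)
    }, logical(3))
    subsample <- data.frame(
      ordering = rownames(draws),
      fraction = rowMeans(draws))
    rownames(subsample) <- NULL
  }
  list(p_press = p_press, p_emg = p_emg, portions = portions,
       comparison = comparison, subsample = subsample)
}

#' prEMG profiles over mode-centered SSD
#'
#' Participant-level means per centered SSD step: prEMG probability (prEMG
#' trials over stop trials at that step), go-locked onset latency,
#' stop-locked peak latency and peak amplitude (latency/amplitude cells only
#' where prEMG exists at that step). Tidy output meant for external
#' smoothing.
#'
#' @param bursts burst table (optionally with a `participant` column).
#' @param step staircase step in ms.
#' @return data.frame with one row per (participant, step).
#' @export
ssdProfiles <- function(bursts, step = 50) {
  bursts <- .withParticipant(bursts)
  st <- bursts[bursts$trial_type == "stop", ]
  out <- do.call(rbind, lapply(split(st, st$participant), function(d) {
    ctr <- (d$ssd - .modalSsd(d$ssd)) / step
    keep <- abs(ctr) <= 3
    d <- d[keep, ]; ctr <- ctr[keep]
    do.call(rbind, lapply(split(seq_len(nrow(d)), ctr), function(i) {
      pr <- i[d$emg_class[i] == "premg"]
      data.frame(participant = d$participant[1],
                 step = ctr[i[1]],
                 n_stop = length(i), n_premg = length(pr),
                 p_premg = length(pr) / length(i),
                 onset_go = if (length(pr)) mean(d$onset_go[pr]) else NA_real_,
                 peak_stop = if (length(pr)) mean(d$peak_stop[pr]) else NA_real_,
                 peak_amp = if (length(pr)) mean(d$peak_amp[pr]) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Prepare the single-trial prEMG table
#'
#' Cleans and transforms prEMG trials for single-trial analysis: drops
#' trials whose peak precedes the stop signal, drops trials whose go-locked
#' onset or stop-locked peak lies outside
#' [Q1 - 2 IQR, Q3 + 2 IQR] of that participant's values
#' (linear-interpolation quartiles), log-transforms the AUC, and
#' orthogonalizes onsets for the SSD by regressing onset on SSD per
#' participant (least squares) and keeping the residuals. Participants with
#' fewer than 3 prEMG trials are flagged and skipped for residualization.
#'
#' @param bursts burst table (optionally with a `participant` column).
#' @return data.frame of cleaned prEMG trials with `onset_resid`,
#'   `log_auc` and `resid_skipped` columns.
#' @export
singleTrialPrepare <- function(bursts) {
  bursts <- .withParticipant(bursts)
  pr <- bursts[bursts$emg_class == "premg", ]
  if (!nrow(pr)) stop("no prEMG trials", call. = FALSE)
  out <- do.call(rbind, lapply(split(pr, pr$participant), function(d) {
    d <- d[!d$pre_stop_peak, ]
    if (!nrow(d)) return(NULL)
    inside <- function(x) {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE)
      iqr <- q[2] - q[1]
      x >= q[1] - 2 * iqr & x <= q[2] + 2 * iqr
    }
    d <- d[inside(d$onset_go) & inside(d$peak_stop), ]
    if (!nrow(d)) return(NULL)
    d$log_auc <- ifelse(d$auc > 0, log(d$auc), NA_real_)
    if (nrow(d) >= 3) {
      d$onset_resid <- stats::resid(stats::lm(onset_go ~ ssd, data = d))
      d$resid_skipped <- FALSE
    } else {
      d$onset_resid <- NA_real_
      d$resid_skipped <- TRUE
    }
    d
  }))
  rownames(out) <- NULL
  out
}

#' Per-participant prEMG peak-latency variability
#'
#' Sample standard deviation (divisor n - 1) of stop-locked prEMG peak
#' latencies per participant (needs at least 2 prEMG trials), with
#' participants flagged as outliers when their sd exceeds Q3 + 2 IQR of the
#' group distribution.
#'
#' @param bursts burst table (optionally with a `participant` column).
#' @return data.frame with `participant`, `n_premg`, `sd_peak`, `outlier`.
#' @export
peakLatencyVariability <- function(bursts) {
  bursts <- .withParticipant(bursts)
  pr <- bursts[bursts$emg_class == "premg", ]
  out <- do.call(rbind, lapply(split(pr, pr$participant), function(d)
    data.frame(participant = d$participant[1], n_premg = nrow(d),
               sd_peak = if (nrow(d) >= 2) stats::sd(d$peak_stop)
                         else NA_real_)))
  rownames(out) <- NULL
  sds <- out$sd_peak[!is.na(out$sd_peak)]
  q <- stats::quantile(sds, c(0.25, 0.75), type = 7)
  out$outlier <- !is.na(out$sd_peak) &
    out$sd_peak > q[2] + 2 * (q[2] - q[1])
  out
}

#' EMG summary block for one participant
#'
#' Counts and detection percentages per trial class (go, successful stop,
#' unsuccessful stop), and the class-wise means of onset latency, peak
#' latency, peak amplitude, motor time, rise time and AUC. Each value is the
#' mean of the per-hand means when both hands contributed trials. Also
#' reports the three prEMG peak-latency estimators and the per-participant
#' sd of the prEMG peak latency.
#'
#' @param bursts burst table for one participant.
#' @param epochs matching z-scored [EpochSet-class] (for the
#'   average-waveform estimator; optional).
#' @return a one-row data.frame; absent estimates are `NA`.
#' @export
emgSummary <- function(bursts, epochs = NULL) {
  cls <- list(go = bursts$trial_type == "go",
              sstop = bursts$outcome == "stop_success",
              ustop = bursts$outcome == "stop_fail")
  blocks <- lapply(names(cls), function(nm) {
    d <- bursts[cls[[nm]], ]
    det <- d[d$detected, ]
    out <- data.frame(
      count = nrow(det),
      pct = if (nrow(d)) 100 * nrow(det) / nrow(d) else NA_real_,
      onset = .handMean(det$onset_go, det$hand),
      peak_go = .handMean(det$peak_go, det$hand),
      peak_amp = .handMean(det$peak_amp, det$hand),
      motor_time = .handMean(det$motor_time, det$hand),
      rise_time = .handMean(det$rise_time, det$hand),
      auc = .handMean(det$auc, det$hand))
    names(out) <- paste0(nm, "_", names(out))
    out
  })
  pr <- bursts[bursts$emg_class == "premg", ]
  est <- data.frame(
    premg_peak_single = premgPeakLatency(bursts, method = "single_trial"),
    premg_peak_waveform = if (!is.null(epochs))
      premgPeakLatency(bursts, epochs, method = "average_waveform")
      else NA_real_,
    premg_peak_mode = premgPeakLatency(bursts, method = "mode_ssd"),
    premg_peak_stop = if (nrow(pr)) .handMean(pr$peak_stop, pr$hand)
                      else NA_real_,
    ustop_peak_stop = {
      us <- bursts[bursts$emg_class == "ustop_emg", ]
      if (nrow(us)) .handMean(us$peak_stop, us$hand) else NA_real_
    },
    premg_peak_sd = if (nrow(pr) >= 2) stats::sd(pr$peak_stop)
                    else NA_real_)
  cbind(do.call(cbind, blocks), est)
}

#' Full participant summary
#'
#' Behavioural block (accuracies, RTs, SSD, SSRT) plus EMG block in one row.
#'
#' @param trials validated trial table for one participant.
#' @param bursts matching burst table.
#' @param epochs matching z-scored [EpochSet-class] (optional).
#' @return a one-row data.frame.
#' @export
participantSummary <- function(trials, bursts, epochs = NULL) {
  beh <- behavioralSummary(trials)
  beh$ssrt <- ssrtIntegration(trials)$ssrt
  cbind(beh, emgSummary(bursts, epochs))
}
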