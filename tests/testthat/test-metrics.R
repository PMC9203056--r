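simpleTrials <- function(goRT, stopResp, ssd) {
  n_go <- length(goRT); n_st <- length(stopResp)
  validateTrialTable(data.frame(
    trial_id = sprintf("t%03d", seq_len(n_go + n_st)),
    block = 1L,
    trial_type = c(rep("go", n_go), rep("stop", n_st)),
    go_onset = seq_len(n_go + n_st) * 3,
    ssd = c(rep(NA_real_, n_go), ssd),
    response_hand = c(ifelse(is.na(goRT), "none", "right"),
                      ifelse(stopResp, "right", "none")),
    rt = c(goRT, ifelse(stopResp, 480, NA_real_)),
    required_hand = "right"))
}

test_that("behavioural summary counts accuracies and omissions", {
  goRT <- c(rep(500, 9), NA)
  tr <- simpleTrials(goRT, c(TRUE, TRUE, FALSE, FALSE), rep(300, 4))
  s <- behavioralSummary(tr)
  expect_equal(s$go_omission_pct, 10)
  expect_equal(s$go_accuracy_pct, 90)
  expect_equal(s$stop_accuracy_pct, 50)
  expect_equal(s$usstop_rt, 480)
  expect_equal(s$mean_ssd, 300)
  expect_error(behavioralSummary(tr[tr$trial_type == "go", ]),
               "no stop trials")
})

test_that("integration SSRT follows the rank rule with omission replacement", {
  goRT <- seq(100, 1000, by = 100)
  tr <- simpleTrials(goRT, rep(c(TRUE, FALSE), 5), rep(300, 10))
  res <- ssrtIntegration(tr)
  expect_equal(res$p_respond, 0.5)
  expect_equal(res$nth_rt, 500)          # ceil(0.5 * 10) = 5th of sorted
  expect_equal(res$ssrt, 200)

  # an omission is replaced by the maximum RT: {100..900, NA} with max 900
  goRT2 <- c(seq(100, 900, by = 100), NA)
  tr2 <- simpleTrials(goRT2, rep(c(TRUE, FALSE), 5), rep(300, 10))
  res2 <- ssrtIntegration(tr2)
  # hand computation: vector {100..900, 900}, 5th smallest = 500
  expect_equal(res2$nth_rt, 500)
  expect_equal(res2$ssrt, 200)

  # choice errors are included in the go distribution
  tr3 <- simpleTrials(goRT, rep(c(TRUE, FALSE), 5), rep(300, 10))
  tr3$response_hand[1] <- "left"
  tr3 <- validateTrialTable(tr3)
  expect_equal(ssrtIntegration(tr3)$nth_rt, 500)

  # p = 1 is undefined and flagged
  tr4 <- simpleTrials(goRT, rep(TRUE, 4), rep(300, 4))
  res4 <- ssrtIntegration(tr4)
  expect_true(res4$undefined)
  expect_true(is.na(res4$ssrt))
})

premgBursts <- function(peaks_stop, ssd, participant = 1) {
  n <- length(peaks_stop)
  data.frame(participant = participant,
             trial_id = sprintf("p%d_s%03d", participant, seq_len(n)),
             block = 1L, trial_type = "stop", outcome = "stop_success",
             hand = rep(c("left", "right"), length.out = n),
             ssd = ssd, rt = NA_real_, detected = TRUE,
             onset_go = ssd + peaks_stop - 40,
             peak_go = ssd + peaks_stop,
             peak_stop = peaks_stop, peak_amp = 3,
             motor_time = NA_real_, rise_time = 40,
             auc = 20, onset_warn = FALSE, emg_class = "premg",
             pre_stop_peak = peaks_stop < 0)
}

test_that("the three prEMG latency estimators behave as documented", {
  b <- premgBursts(c(150, 170), c(300, 300))
  expect_equal(premgPeakLatency(b, method = "single_trial"), 160)
  expect_equal(premgPeakLatency(b, method = "mode_ssd"), 160)
  # modal SSD with a tie goes to the lowest SSD
  b2 <- premgBursts(c(100, 200), c(250, 300))
  expect_equal(premgPeakLatency(b2, method = "mode_ssd"), 100)
  # no prEMG trials: absent value
  b3 <- b; b3$emg_class <- "none"
  expect_true(is.na(premgPeakLatency(b3, method = "single_trial")))

  # identical epochs: all three methods agree exactly
  time <- -0.2 + (0:899) / 500
  x <- rep(0, 900)
  pk <- which.min(abs(time - 0.45))
  x[(pk - 20):pk] <- seq(1.3, 4, length.out = 21)
  d <- rbind(x, x)
  tr <- data.frame(trial_id = c("s1", "s2"), block = 1L,
                   trial_type = "stop", go_onset = c(3, 6), ssd = 300,
                   response_hand = "none", rt = NA_real_,
                   required_hand = "right", outcome = "stop_success",
                   hand = "right")
  ep <- makeEpochSet(d, trials = tr)
  bb <- extractBursts(ep)
  expect_equal(bb$emg_class, c("premg", "premg"))
  st <- premgPeakLatency(bb, method = "single_trial")
  avg <- premgPeakLatency(bb, ep, method = "average_waveform")
  md <- premgPeakLatency(bb, method = "mode_ssd")
  expect_equal(st, md)
  expect_equal(st, avg, tolerance = 2 + 1e-8)  # waveform peak on the grid
})

test_that("the prEMG estimators agree on the simulated cohort", {
  co <- testCohort()
  for (p in unique(co$bursts$participant)) {
    b <- co$bursts[co$bursts$participant == p, ]
    if (!any(b$emg_class == "premg")) next
    st <- premgPeakLatency(b, method = "single_trial")
    av <- premgPeakLatency(b, co$epochs[[p]], method = "average_waveform")
    md <- premgPeakLatency(b, method = "mode_ssd")
    expect_lt(abs(st - av), 25)
    if (!is.na(md)) expect_lt(abs(st - md), 30)
  }
})

test_that("inhibition functions count presses and EMG per centered SSD", {
  # one step: 2 fails, 1 prEMG success, 1 clean success
  b <- premgBursts(c(150, 150, 150, 150), rep(300, 4))
  b$outcome <- c("stop_fail", "stop_fail", "stop_success", "stop_success")
  b$emg_class <- c("ustop_emg", "ustop_emg", "premg", "none")
  b$detected <- c(TRUE, TRUE, TRUE, FALSE)
  inh <- inhibitionFunctions(b)
  expect_equal(inh$group$p_press, 0.5)
  expect_equal(inh$group$p_emg, 0.75)

  # all responded: both probabilities 1 at every populated step
  b2 <- premgBursts(rep(100, 6), c(250, 250, 300, 300, 350, 350))
  b2$outcome <- "stop_fail"; b2$emg_class <- "ustop_emg"
  inh2 <- inhibitionFunctions(b2)
  expect_true(all(inh2$group$p_press == 1))
  expect_true(all(inh2$group$p_emg == 1))

  # p(EMG|stop) >= p(press|stop) everywhere on the simulated cohort
  co <- testCohort()
  inh3 <- inhibitionFunctions(co$bursts)
  expect_true(all(inh3$per_participant$p_emg >=
                  inh3$per_participant$p_press))
  expect_true(all(abs(inh3$per_participant$step) <= 3))
})

test_that("go-distribution partitions split at the stated percentiles", {
  goRT <- (1:10) * 100
  tr <- simpleTrials(goRT, c(TRUE, FALSE, TRUE, FALSE), rep(300, 4))
  b <- premgBursts(c(150, 150, 150, 150), rep(300, 4))
  b$outcome <- tr$outcome[tr$trial_type == "stop"]
  b$emg_class <- ifelse(b$outcome == "stop_fail", "ustop_emg", "premg")
  # p_press = 0.5 -> fast = {100..500}; force p_emg = 0.8 via class mix
  b$emg_class[4] <- "premg"; b$outcome[4] <- "stop_success"
  b$outcome <- c("stop_fail", "stop_fail", "stop_success", "stop_success")
  b$emg_class <- c("ustop_emg", "ustop_emg", "premg", "none")
  # p_press = .5, p_emg = .75 -> k1 = 5, k2 = 8
  p <- partitionGoDistribution(tr, b, level = "rt")
  expect_equal(p$p_press, 0.5)
  expect_equal(p$portions$mean[p$portions$portion == "fast"], 300)
  expect_equal(p$portions$n, c(5, 3, 2))
  expect_equal(sum(p$portions$n), 10)    # partitions tile the distribution
  expect_equal(p$portions$mean[p$portions$portion == "medium"],
               mean(c(600, 700, 800)))
  expect_equal(p$portions$mean[p$portions$portion == "slow"],
               mean(c(900, 1000)))

  # tiling holds on the simulated cohort for every participant
  co <- testCohort()
  for (pid in unique(co$trials$participant)) {
    trs <- co$trials[co$trials$participant == pid, ]
    bs <- co$bursts[co$bursts$participant == pid, ]
    pp <- partitionGoDistribution(trs, bs, level = "rt")
    expect_equal(sum(pp$portions$n),
                 sum(trs$trial_type == "go" & !is.na(trs$rt)))
    pe <- partitionGoDistribution(trs, bs, level = "emg_onset",
                                  n_subsamples = 50)
    expect_equal(sum(pe$portions$n), sum(bs$emg_class == "go_emg"))
    expect_true(all(pe$subsample$fraction >= 0 &
                    pe$subsample$fraction <= 1))
  }
})

test_that("under the independent race, fast go trials match unsuccessful
           stops", {
  partDiff <- function(cfg) {
    beh <- simulateBehavior(cfg)
    vapply(split(beh$trials, beh$trials$participant), function(d) {
      st <- d[d$trial_type == "stop", ]
      pseudo <- data.frame(trial_type = "stop", outcome = st$outcome,
                           emg_class = "none", ssd = st$ssd)
      p <- partitionGoDistribution(d, pseudo, level = "rt")
      p$portions$mean[p$portions$portion == "fast"] - p$comparison$mean[1]
    }, numeric(1))
  }
  # at a fixed SSD the fast-go portion and the unsuccessful-stop RTs are
  # the same censored distribution: means agree up to Monte-Carlo error
  fixed <- partDiff(simConfig(n_participants = 40, p_trigger_failure = 0,
                              p_go_failure = 0, staircase_init = 350,
                              staircase_min = 350, staircase_max = 350,
                              seed = 63))
  expect_lt(abs(mean(fixed)), 3 * sd(fixed) / sqrt(length(fixed)))
  # with staircase-varying SSDs the aggregate-percentile split is only
  # approximate, and its bias has a known sign: fast go trials are faster
  tracked <- partDiff(simConfig(n_participants = 20, seed = 61))
  expect_lt(mean(tracked), 0)
  expect_lt(abs(mean(tracked)), 30)
})

test_that("single-trial preparation residualizes, logs and drops outliers", {
  # onsets exactly linear in SSD: all residuals zero
  b <- premgBursts(rep(150, 6), c(250, 300, 350, 250, 300, 350))
  b$onset_go <- 100 + 0.9 * b$ssd
  st <- singleTrialPrepare(b)
  expect_true(all(abs(st$onset_resid) < 1e-9))
  expect_false(any(st$resid_skipped))

  # auc = 1 -> log_auc = 0
  b$auc <- 1
  expect_true(all(singleTrialPrepare(b)$log_auc == 0))

  # a pre-stop peak is excluded
  b2 <- premgBursts(c(-20, 150, 160, 170, 150), rep(300, 5))
  expect_false(any(singleTrialPrepare(b2)$peak_stop < 0))

  # hand-computed 2-IQR outlier rule (type-7 quartiles) drops exactly one
  onsets <- c(400, 410, 420, 430, 440, 450, 1000)
  q <- quantile(onsets, c(0.25, 0.75), type = 7)
  stopifnot(1000 > q[2] + 2 * (q[2] - q[1]))  # oracle: last value is out
  b3 <- premgBursts(rep(150, 7), rep(300, 7))
  b3$onset_go <- onsets
  st3 <- singleTrialPrepare(b3)
  expect_equal(nrow(st3), 6)
  expect_false(1000 %in% st3$onset_go)

  # fewer than 3 prEMG trials: residualization skipped and flagged
  b4 <- premgBursts(c(150, 160), c(250, 300))
  st4 <- singleTrialPrepare(b4)
  expect_true(all(st4$resid_skipped))
  expect_true(all(is.na(st4$onset_resid)))
})

test_that("peak-latency variability uses sample sd and flags outliers", {
  b <- premgBursts(c(150, 170), c(300, 300))
  v <- peakLatencyVariability(b)
  expect_equal(v$sd_peak, sd(c(150, 170)))
  expect_equal(v$sd_peak, 14.14, tolerance = 0.01)
  b2 <- premgBursts(rep(160, 5), rep(300, 5))
  expect_equal(peakLatencyVariability(b2)$sd_peak, 0)
  # one participant with a single trial gets an absent value
  b3 <- rbind(premgBursts(c(150, 170), c(300, 300), participant = 1),
              premgBursts(155, 300, participant = 2))
  v3 <- peakLatencyVariability(b3)
  expect_true(is.na(v3$sd_peak[v3$participant == 2]))
})

test_that("SSD profiles stay tidy and bounded", {
  b <- premgBursts(c(150, 160), c(300, 300))
  extra <- premgBursts(rep(120, 4), c(250, 350, 250, 350))
  extra$emg_class <- "none"; extra$detected <- FALSE
  prof <- ssdProfiles(rbind(b, extra))
  expect_true(all(prof$p_premg >= 0 & prof$p_premg <= 1))
  expect_true(all(is.na(prof$peak_stop[prof$n_premg == 0])))
  expect_true(all(!is.na(prof$peak_stop[prof$n_premg > 0])))
  co <- testCohort()
  prof2 <- ssdProfiles(co$bursts)
  expect_true(all(prof2$p_premg >= 0 & prof2$p_premg <= 1))
})

test_that("hand averaging is the mean of per-hand means", {
  b <- premgBursts(c(100, 200, 300), c(300, 300, 300))
  b$hand <- c("left", "left", "right")
  s <- emgSummary(b)
  # mean of hand means: mean(c(mean(100, 200), 300)) = 225, not 200
  expect_equal(s$premg_peak_stop, 225)
  expect_equal(s$premg_peak_single, 200)  # single-trial mean is unweighted
})
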