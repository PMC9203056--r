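makeRec <- function(x, rate, hands = c(ch = "right")) {
  m <- matrix(x, nrow = 1)
  rownames(m) <- names(hands)
  new("ContinuousRecording", samples = m, rate = rate,
      channels = names(hands), hands = hands,
      events = data.frame(time = numeric(0), code = character(0)),
      meta = list())
}

oneTrial <- function(onset, type = "go", ssd = NA_real_, rt = 500) {
  validateTrialTable(data.frame(
    trial_id = "t01", block = 1L, trial_type = type, go_onset = onset,
    ssd = ssd, response_hand = if (is.na(rt)) "none" else "right",
    rt = rt, required_hand = "right"))
}

test_that("bandpass attenuates out-of-band and passes in-band sinusoids", {
  rate <- 5000
  t <- seq(0, 4, by = 1 / rate)
  cfg <- preprocessConfig()
  rms <- function(x) sqrt(mean(x^2))
  lowf <- bandpassFilter(makeRec(sin(2 * pi * 5 * t), rate), cfg)
  expect_lt(rms(lowf@samples[1, ]), 0.05 * rms(sin(2 * pi * 5 * t)))
  inband <- bandpassFilter(makeRec(sin(2 * pi * 100 * t), rate), cfg)
  # drop filter edge transients before comparing
  mid <- seq(rate, 3 * rate)
  expect_equal(rms(inband@samples[1, mid]), rms(sin(2 * pi * 100 * t)[mid]),
               tolerance = 0.05)
  zero <- bandpassFilter(makeRec(rep(0, rate), rate), cfg)
  expect_true(all(zero@samples == 0))
  expect_error(bandpassFilter(makeRec(rnorm(100), 400), cfg), "too low")
})

test_that("resampling preserves constants, duration and frequency content", {
  rate <- 5000
  const <- resampleRecording(makeRec(rep(3, 10 * rate), rate), 500)
  expect_equal(samplingRate(const), 500)
  expect_true(all(const@samples == 3))
  expect_lte(abs(ncol(const@samples) - 5000), 1)
  # 50 Hz sinusoid recovered by spectral peak after decimation
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  res <- resampleRecording(makeRec(sin(2 * pi * 50 * t), rate), 500)
  x <- res@samples[1, ]
  spec <- Mod(stats::fft(x))[1:(length(x) / 2)]
  freq <- (seq_along(spec) - 1) / (length(x) / 500)
  expect_equal(freq[which.max(spec[-1]) + 1], 50, tolerance = 0.2)
  expect_error(resampleRecording(makeRec(rnorm(100), 500), 1000),
               "upsampling")
})

test_that("epoching windows, t = 0 sample, and edge rejection behave", {
  rate <- 500
  rec <- makeRec(rnorm(10 * rate), rate)
  ep <- epochRecording(rec, oneTrial(5.0))
  expect_equal(ncol(epochData(ep)), 900)
  expect_equal(min(epochTime(ep)), -0.2)
  expect_equal(max(epochTime(ep)), 1.598)
  expect_true(any(abs(epochTime(ep)) < 1e-12))
  expect_equal(processingStage(ep), "filtered")

  late <- epochRecording(rec, oneTrial(9.9))
  expect_equal(rejectedReasons(late)[1], "edge")

  # impulse at 5.3 s with go onset at 5.0 s peaks at +0.3 s on the axis
  x <- rep(0, 10 * rate); x[round(5.3 * rate) + 1] <- 1
  imp <- epochRecording(makeRec(x, rate), oneTrial(5.0))
  expect_equal(epochTime(imp)[which.max(epochData(imp)[1, ])], 0.3,
               tolerance = 1 / rate)
})

test_that("baseline rejection flags high mean rectified baselines", {
  rate <- 500
  high <- makeRec(rep(150, 3 * rate), rate)
  ep <- suppressMessages(
    rejectHighBaseline(epochRecording(high, oneTrial(1.0))))
  expect_equal(rejectedReasons(ep)[1], "baseline")
  low <- makeRec(rep(50, 3 * rate), rate)
  ep2 <- suppressMessages(
    rejectHighBaseline(epochRecording(low, oneTrial(1.0))))
  expect_true(is.na(rejectedReasons(ep2)[1]))
  expect_error(rejectHighBaseline(rmsEnvelope(ep2)), "filtered")
})

test_that("injected noisy baselines are rejected at the injection rate", {
  cfg <- simConfig(n_participants = 1, n_go = 150, n_stop = 50,
                   n_blocks = 2, seed = 33)
  emg <- emgConfig(rate = 2000, p_noisy_baseline = 0.1)
  sim <- simulateCohort(cfg, emg)
  tr <- sim$trials
  rec <- bandpassFilter(sim$recordings[[1]], preprocessConfig())
  rec <- resampleRecording(rec, 500)
  ep <- suppressMessages(rejectHighBaseline(epochRecording(rec, tr)))
  n_inj <- sum(sim$truth$noisy_baseline)
  n_rej <- sum(!is.na(rejectedReasons(ep)))
  expect_lte(abs(n_rej - n_inj), 0.25 * max(n_inj, 4))
})

test_that("RMS envelope matches constants, alternation and a naive loop", {
  ep <- makeEpochSet(matrix(rep(-2, 900), nrow = 1), stage = "filtered")
  out <- rmsEnvelope(ep)
  expect_true(all(abs(epochData(out) - 2) < 1e-12))
  expect_equal(processingStage(out), "rms")

  alt <- makeEpochSet(matrix(rep(c(1, -1), 450), nrow = 1),
                      stage = "filtered")
  expect_true(all(abs(epochData(rmsEnvelope(alt)) - 1) < 1e-12))

  set.seed(5)
  x <- matrix(rnorm(3 * 900), nrow = 3)
  got <- epochData(rmsEnvelope(makeEpochSet(x, stage = "filtered"),
                               halfwidth = 5))
  for (r in 1:3)
    expect_equal(got[r, ], oracleRms(x[r, ], 5), tolerance = 1e-12)
  expect_error(rmsEnvelope(makeEpochSet(x, stage = "filtered"),
                           halfwidth = 900), "halfwidth")
})

test_that("baseline normalization divides by the per-trial baseline mean", {
  x <- matrix(2, nrow = 1, ncol = 900)
  x[1, 200] <- 6
  ep <- baselineNormalize(makeEpochSet(x, stage = "rms"))
  expect_equal(epochData(ep)[1, 200], 3)
  bl <- which(epochTime(ep) < 0)
  expect_equal(mean(epochData(ep)[1, bl]), 1)
  # zero baseline rejects the trial instead of dividing by zero
  z <- matrix(0, nrow = 1, ncol = 900); z[1, 500] <- 5
  out <- baselineNormalize(makeEpochSet(z, stage = "rms"))
  expect_equal(rejectedReasons(out)[1], "flat baseline")
})

test_that("block z-scoring standardizes each block with population sd", {
  # two identical epochs of {0, 2}: block mean 1, population sd 1
  d <- matrix(c(0, 2, 0, 2), nrow = 2, byrow = TRUE)
  tr <- data.frame(trial_id = c("a", "b"), block = 1L, trial_type = "go",
                   go_onset = c(1, 2), ssd = NA_real_,
                   response_hand = "right", rt = 500,
                   required_hand = "right", outcome = "go_correct",
                   hand = "right")
  ep <- makeEpochSet(d, rate = 500, stage = "baseline_normalized",
                     trials = tr, baseline = c(-0.2, 0))
  out <- zscoreByBlock(ep)
  expect_equal(epochData(out), matrix(c(-1, 1, -1, 1), nrow = 2,
                                      byrow = TRUE))

  # blocks with different scales are standardized independently
  set.seed(9)
  d2 <- rbind(matrix(rnorm(2 * 900, 0, 5), nrow = 2),
              matrix(rnorm(2 * 900, 10, 0.1), nrow = 2))
  tr2 <- tr[c(1, 1, 1, 1), ]
  tr2$trial_id <- letters[1:4]
  tr2$block <- c(1L, 1L, 2L, 2L)
  ep2 <- makeEpochSet(d2, rate = 500, stage = "baseline_normalized",
                      trials = tr2)
  out2 <- zscoreByBlock(ep2)
  for (blk in 1:2) {
    v <- as.numeric(epochData(out2)[tr2$block == blk, ])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
})

test_that("stage order is enforced", {
  x <- matrix(rnorm(900), nrow = 1)
  expect_error(zscoreByBlock(makeEpochSet(x, stage = "filtered")),
               "stage")
  expect_error(baselineNormalize(makeEpochSet(x, stage = "filtered")),
               "stage")
  expect_error(rmsEnvelope(makeEpochSet(x, stage = "zscored")), "stage")
})

test_that("filter-then-resample agrees with directly synthesized 500 Hz", {
  # band-limited signal: chain output should match a direct synthesis
  rate <- 5000
  t_hi <- seq(0, 4 - 1 / rate, by = 1 / rate)
  f <- 80
  rec <- makeRec(sin(2 * pi * f * t_hi), rate)
  out <- resampleRecording(bandpassFilter(rec, preprocessConfig()), 500)
  t_lo <- t_hi[seq(1, length(t_hi), by = 10)]
  direct <- sin(2 * pi * f * t_lo)
  mid <- seq(500, 1500)
  expect_equal(out@samples[1, mid], direct[mid], tolerance = 0.01)
})
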