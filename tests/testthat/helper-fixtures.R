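# Shared simulated cohort, built once per test run. Small enough to keep the
# suite fast, large enough to measure detection and latency statistics:
# 3 participants x (120 go + 40 stop) trials, EMG synthesized at 2000 Hz.

.fixture_env <- new.env(parent = emptyenv())

testCohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  cfg <- simConfig(n_participants = 3, n_go = 120, n_stop = 40,
                   n_blocks = 2, seed = 101)
  emg <- emgConfig(rate = 2000)
  sim <- simulateCohort(cfg, emg)
  bursts <- list(); epochs <- list()
  for (p in seq_len(cfg$n_participants)) {
    tr <- sim$trials[sim$trials$participant == p, ]
    ep <- suppressMessages(preprocessEmg(sim$recordings[[p]], tr))
    epochs[[p]] <- ep
    bursts[[p]] <- cbind(participant = p, extractBursts(ep))
  }
  .fixture_env$cohort <- list(
    config = cfg, emg = emg, trials = sim$trials, truth = sim$truth,
    recordings = sim$recordings, epochs = epochs,
    bursts = do.call(rbind, bursts))
  .fixture_env$cohort
}

# small deterministic trial table used by io tests
tinyTrials <- function() {
  validateTrialTable(data.frame(
    trial_id = sprintf("t%02d", 1:4),
    block = 1L,
    trial_type = c("go", "go", "stop", "stop"),
    go_onset = c(2, 5, 8, 11),
    ssd = c(NA, NA, 250, 300),
    response_hand = c("left", "right", "none", "right"),
    rt = c(430, 520, NA, 480),
    required_hand = c("left", "right", "left", "right")))
}
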