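seed: 1.0
sim:
  n_participants: 46.0
  n_go: 684.0
  n_stop: 216.0
  n_blocks: 6.0
  go_mean: 546.0
  go_sd: 114.0
  stop_mean: 202.0
  stop_sd: 31.0
  between_go_sd: 77.0
  between_stop_sd: 21.0
  p_go_failure: 0.016
  p_trigger_failure: 0.013
  p_choice_error: 0.007
  staircase_init: 250.0
  staircase_step: 50.0
  staircase_min: 100.0
  staircase_max: 800.0
  motor_time_mean: 57.0
  motor_time_sd: 13.0
  response_window: 1000.0
  dependence: independent
  coupling: 0.5
  seed: 1.0
emg:
  rate: 5000.0
  noise_sd: 2.0
  burst_amp: 25.0
  burst_rise: 52.0
  burst_fall: 60.0
  rise_shape: 0.4
  premg_trunc_mean: 165.0
  premg_trunc_sd: 25.0
  premg_amp_cap: 0.8
  carrier_band:
  - 20.0
  - 250.0
  p_noisy_baseline: 0.0
  noisy_baseline_uV: 250.0
preprocess:
  band:
  - 20.0
  - 250.0
  filter_order: 2.0
  target_rate: 500.0
  epoch_window:
  - -0.2
  - 1.6
  baseline_window:
  - -0.2
  - 0.0
  reject_baseline_uV: 100.0
  rms_halfwidth: 5.0
  zero_phase: yes
detect:
  threshold: 1.2
  onset_run_ms: 8.0
  search_window:
  - 0.0
  - 1.6
reliability:
  n_perm: 10000.0
  titration_reps: 1000.0
  titration_min: 6.0
  method: pearson
inputs:
  recordings: ~
  trials: ~
  format: brainvision
events:
  go: go
  stop: stop
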