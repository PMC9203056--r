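---
title: "Quantifying action stopping from partial-response EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying action stopping from partial-response EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the stop signal task, participants respond to a go signal with a left- or
right-hand button press and must withhold that response when a stop signal
follows after a variable stop signal delay (SSD). The canonical latency
measure of stopping, the stop signal reaction time (SSRT), is model-derived:
under the independent horse race model the go and stop processes race, and
the SSRT is inferred from the go-RT distribution, the probability of
responding on stop trials, and the SSDs. Surface EMG over the responding
muscles (typically *abductor pollicis brevis*) offers a physiological
complement: in a fraction of successfully stopped trials the muscle still
produces a small burst — a response initiated by the go signal and aborted
before the button press. The peak of this partial-response EMG (prEMG),
expressed relative to stop-signal onset, is a single-trial marker of when
stopping took effect at the periphery.

`premg` implements the full analysis chain from continuous bipolar EMG and a
trial table to single-trial stopping latencies, SSRT, horse-race
diagnostics, variability, and reliability, plus a race-model simulator with
ground truth so that every stage is testable without any recorded data.

## Preprocessing model

The chain follows the standard surface-EMG recipe, in a fixed stage order
that the `EpochSet` container enforces
(`filtered -> rms -> baseline_normalized -> zscored`):

1. **Bandpass** 20–250 Hz, second-order Butterworth, at the native sampling
   rate. The filter is applied forward–backward (zero phase) by default:
   causal filtering would systematically delay onset and peak latencies,
   which are the quantities of interest. A causal mode is available via
   `preprocessConfig(zero_phase = FALSE)` for users who need to match
   online processing.
2. **Resample** to 500 Hz by decimation after filtering. The 250 Hz band
   edge sits exactly at the new Nyquist frequency; this is acceptable
   because filtering precedes resampling.
3. **Epoch** from −0.2 to 1.6 s around go-signal onset (900 samples; the
   axis contains a sample at exactly t = 0), taking the channel of the
   trial's required hand. The channel-to-hand map is explicit configuration
   — it is never inferred from channel labels. Epochs that exceed the
   recording bounds are flagged `edge` and excluded from all downstream
   metrics.
4. **Baseline rejection**: trials whose mean *rectified* filtered amplitude
   over −0.2 to 0 s exceeds 100 µV are flagged. Rectification makes the
   criterion sign-invariant; whether the original rule rectified first is
   not documented anywhere we know of, and for zero-mean bandpassed EMG the
   two readings differ radically (the unrectified mean is ≈ 0 for any
   noise level), so the rectified reading is the only usable one.
5. **RMS envelope** over a centred ±5-sample window (~22 ms at 500 Hz).
   At epoch borders the window shrinks instead of padding, so no fabricated
   samples enter the envelope. The "±5 data points" are post-resampling
   samples; the transform is defined on the 500 Hz epochs.
6. **Baseline normalization**: each trial's full time-course is divided by
   its own baseline-window mean (so the normalized baseline mean is exactly
   1). A zero baseline mean rejects the trial (`flat baseline`) rather than
   dividing by zero.
7. **Block-wise z-scoring**: for each (hand, block) group the kept epochs
   are concatenated into one vector, and every sample is transformed by the
   grand mean and *population* standard deviation (divisor N) of that
   vector. At typical block sizes (~10^5 samples) the difference from the
   sample sd is far below numerical noise; the population convention makes
   the "concatenated block has mean 0, sd 1" identity exact, and the test
   suite asserts it at 1e-9.

## Burst detection

A burst is detected when any z-scored envelope sample within the search
window exceeds 1.2 (z units). Because the envelopes are standardized, the
threshold is constant across participants. Two deliberate restrictions:

* The default search window is 0–1.6 s post-go. A literal "any data point"
  rule would let baseline noise before the go signal trigger detection;
  the restriction is configuration (`detectionConfig(search_window = ...)`)
  and is recorded in the report.
* One burst per trial: the global maximum of the search window defines the
  peak (earliest index on exact ties — ties are measure-zero on real data
  but the tie-break is deterministic and documented). Multi-burst epochs
  are not segmented.

The onset is traced backwards from the peak until a run of at least 8 ms of
consecutive sub-threshold samples (4 samples at 500 Hz) is found; the onset
is the first supra-threshold sample after that run, i.e. the earliest sample
of the detected burst. If no such run exists before the window start, the
onset is set to the window start and the trial carries a warning flag.

Derived per-trial measures: go-locked onset and peak latency (ms),
stop-locked peak (`peak_go − SSD`; may be negative, in which case the trial
is *flagged*, not dropped — exclusion happens only in the single-trial
preparation), peak amplitude (z), motor time (RT − onset), rise time
(peak − onset), and AUC (plain cumulative sum of envelope amplitudes from
onset to peak). Trial classes: `go_emg`, `ustop_emg` (unsuccessful stop),
`premg` (successful stop with a burst), `none`.

## Behavioural metrics

**Integration SSRT.** The go-RT vector includes choice-error RTs, and each
go omission is replaced by the participant's maximum go RT. With
p = P(response | stop), the SSRT is `sort(goRT)[ceiling(p * n)] − mean(SSD)`.
The `ceiling(p·n)` rank on the ascending vector is the consensus-guide
convention; p = 0 or 1 yields a flagged undefined value.

**prEMG peak latency** has three estimators: the mean of per-trial
stop-locked peaks (`single_trial`), the peak of the point-wise mean
stop-locked envelope (`average_waveform`), and the mean of per-trial peaks
at the participant's modal SSD (`mode_ssd`). Modal-SSD ties go to the lowest
SSD. For the waveform estimator the peak is searched where at least half the
contributing trials cover the stop-locked time point, so the sparsely
covered tail of the shifted epochs cannot dominate the average. The mode
estimator uses per-trial peaks (not a waveform at that SSD); with identical
epochs all three estimators agree exactly, which the tests assert.

**Inhibition functions.** SSDs are centred per participant on the modal SSD
(ties toward the lowest) in staircase-step units, keeping steps −3…+3.
p(press | stop) counts unsuccessful stops; p(EMG | stop) counts unsuccessful
stops *plus* successful stops with prEMG — every pressed trial necessarily
produced muscle activity, so the set inclusion
p(EMG|stop) ≥ p(press|stop) holds by construction at every step, and the
tests check it exactly.

**Context-independence partitions.** The go distribution (RTs, or go-EMG
onsets) is sorted and split at `k1 = ceiling(p_press · n)` and
`k2 = ceiling(p_emg · n)` into fast / medium / slow portions that tile the
distribution exactly. Under the race model the fast portion should match
unsuccessful-stop trials and the medium portion should match prEMG trials.
The optional subsample mode redraws size-matched subsets from the fast and
medium portions and reports the fraction of draws preserving each ordering,
so unequal trial counts cannot drive the comparison.

**Single-trial preparation.** prEMG trials are cleaned by (i) dropping
trials whose peak precedes the stop signal, (ii) dropping trials whose
go-locked onset or stop-locked peak falls outside
[Q1 − 2·IQR, Q3 + 2·IQR] of that participant's values
(linear-interpolation quartiles, R type 7), then (iii) log-transforming the
AUC and (iv) regressing onset on SSD per participant (ordinary least
squares — the regression form is not documented in the source analyses, and
the near-linear coupling of onset with SSD makes the linear form the
natural choice) and keeping residuals. Cleaning precedes residualization so
outliers cannot leverage the fitted line. Participants with fewer than 3
prEMG trials are flagged and skipped for residualization.

**Variability** is the sample sd (divisor n−1; the divisor is a convention
choice we document rather than inherit) of stop-locked prEMG peaks per
participant, with group-level outliers flagged above Q3 + 2·IQR.

## Reliability

Split-half reliability is permutation-based: per permutation each
participant's trials are split into random halves (⌊n/2⌋ and ⌈n/2⌉ for odd
counts), half-means are correlated across participants (Pearson by default,
Spearman via config), and the correlation is corrected with the
Spearman–Brown prophecy formula r' = 2r/(1+r). The summary is the mean, sd,
and 2.5/97.5 percentiles over permutations (10,000 by default). Negative
corrected values are reported with a flag, never truncated. The titration
analysis repeats this at increasing per-participant trial counts k
(default from 6), keeping only participants with ≥ k trials and subsampling
exactly k trials without replacement per permutation; the curve truncates
below 3 eligible participants.

The suite checks the estimator against a closed-form oracle: for
between-subject sd b and within-subject sd w, the expected corrected
reliability of n-trial means is 2r/(1+r) with
r = b² / √((b² + w²/⌊n/2⌋)(b² + w²/⌈n/2⌉)).

## The simulator

The generator defines the study conditions under which the package is
tested; its defaults are fixed once:

* Design: 46 participants × (684 go + 216 stop) trials in 6 blocks,
  alternating hands, a go-only run-in of 10 trials, 1000 ms response
  window.
* Race: go finishing times ~ Normal(546, 114) ms with participant means
  jittered by sd 77; stop latencies ~ Normal(202, 31) ms, jittered by
  sd 21. Go failures 1.6%, trigger failures 1.3% (a triggered-failure stop
  trial responds whenever the go process was initiated). Choice errors at
  0.7% reproduce the observed error percentage; the error probability is a
  generator addition needed so the `go_error` outcome and its inclusion in
  the SSRT go distribution are exercised.
* Staircase: SSD starts at 250 ms, ±50 ms per stop outcome, clamped to
  100–800 ms, tracked across hands in presentation order.
* EMG: two channels of band-limited (20–250 Hz) Gaussian noise
  (sd 2 µV) at 5000 Hz by default. Every initiated response adds a burst:
  the envelope rises from the true EMG onset (RT minus a motor-time draw,
  Normal(57, 13) ms) over 52 ms as `x^0.4` of elapsed fraction, then decays
  exponentially (60 ms). The concave rise mimics the steep initial
  recruitment of real bursts; numerically it makes the 1.2 z threshold
  crossing fall within a few ms of true activation, roughly cancelling the
  ~10 ms leftward spread of the ±5-sample RMS window, so detected motor
  times stay within a few ms of the configured mean. Burst amplitude is
  25 µV with 15% log-normal trial jitter.
* prEMG rule (the generator's own model — the phenomenon is observed, not
  generatively defined, in the literature): a successful stop trial
  produces a truncated burst iff its would-be EMG onset precedes
  SSD + peripheral stop latency, with the peripheral latency drawn from
  Normal(165, 25) ms. The truncated burst peaks at that moment, decays
  twice as fast as a full burst, and its amplitude scales with
  `sqrt(accumulation / rise)`, capped at 0.8 of the full amplitude — so
  every prEMG burst is weaker than every comparable full burst, and
  detected prEMG frequency lands in the ~15–25% regime of the discovery
  dataset (it is configurable over the wider range reported across
  datasets via `premg_trunc_mean` and `premg_amp_cap`).
* Dependence switch: `independent` keeps the peripheral stop latency
  independent of the go process (race-model null); `onset_coupled` adds a
  positive coupling between the trial's EMG-onset deviation and its
  peripheral stop latency, emulating the positive single-trial
  onset–peak association reported in this literature.
* Seeding: one global seed expands into per-participant streams
  (participant-level seeds drawn once from the global stream), so any
  subset of participants is reproducible in isolation.

What the generator does **not** emulate: baseline muscle-tone drift,
movement artifacts, cross-talk from antagonist muscles, amplifier
saturation, or SSD-dependent strategic slowing. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every pathology of laboratory EMG; the baseline-rejection
path is exercised through an explicit contamination option
(`p_noisy_baseline`) that injects high-amplitude baseline noise.

## Numerical choices and degenerate inputs

* Latencies are reported in ms, recordings and epoch axes in s; the
  conversion happens once, at burst extraction.
* Missing values are written as empty fields in all outputs; numeric
  columns round-trip at full double precision (17 significant digits).
* Zero-variance z-scoring groups and empty search windows raise errors;
  flat baselines and out-of-bounds epochs reject the trial with a reason
  that propagates to the report.
* Detection uses a strict inequality (`> 1.2`); a sample at exactly
  threshold does not trigger.
* The marker scheme aligning events with the recording is explicit
  configuration (`events:` section), since no universal convention exists;
  epoching itself uses the trial table's go onsets.

## Problem sizes used by the test suite

The shared test cohort is 3 participants × (120 go + 40 stop) trials with
EMG synthesized at 2000 Hz — large enough to measure detection rates,
latency biases, and motor-time recovery with sub-ms standard errors, while
keeping the suite fast. Staircase convergence and SSD equilibrium are
checked on the full 46 × 900 design, averaged over three replicate cohorts
to shrink the cohort-level Monte-Carlo error (the between-subject go jitter
alone puts ~11 ms of sd on a single cohort's mean SSD). SSRT recovery uses
100 behaviour-only participants with 600 go / 200 stop trials each; the
reliability checks use 46 simulated participants with the 6–32 trial-count
ladder. These sizes are the package's own choices for precise yet quick
verification.

## Known limitations

* The detector assumes one burst per epoch; double responses merge into
  whichever lobe carries the global maximum.
* Onset detection is threshold-based: onsets are systematically a few ms
  late relative to true activation (and can be a few ms early, bounded by
  the RMS half-window, when smoothing spreads a steep burst); latency
  *differences* across conditions are unaffected.
* prEMG-based estimates are computed on the detected subset of stopped
  trials; like their empirical counterparts they are truncated
  distributions, and the simulator makes that selection explicit
  (ground-truth prEMG means sit a little above the peripheral-latency
  parameter because slower peripheral stops are more likely to leave a
  detectable burst).
* The BrainVision reader supports INT_16 and IEEE_FLOAT_32 multiplexed or
  vectorized data — the variants produced by the target amplifier family —
  not the full format zoo.
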