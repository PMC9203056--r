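Package: premg
Title: Partial-Response Electromyography Analysis for the Stop Signal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify action stopping from surface electromyography
    (EMG) recorded during the stop signal task. Implements the full
    partial-response EMG (prEMG) pipeline: reading continuous bipolar EMG
    (BrainVision or delimited text) and trial tables, bandpass filtering,
    resampling, epoching, artifact rejection, RMS-envelope computation,
    baseline normalization and block-wise z-scoring, threshold-based burst
    detection with backward onset tracing, single-trial stopping latencies,
    integration-method stop signal reaction time (SSRT), behaviour- and
    EMG-based inhibition functions, horse-race context-independence
    partitions, single-trial data preparation, latency variability, and
    permutation split-half reliability with Spearman-Brown correction.
    A built-in independent-race simulator with an adaptive stop-signal-delay
    staircase and synthetic EMG provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io-recording.R'
    'io-trials.R'
    'io-outputs.R'
    'preprocess.R'
    'burst.R'
    'metrics.R'
    'reliability.R'
    'simulate.R'
    'pipeline.R'
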