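Package: stopBeta
Title: Single-Trial Analysis of Action-Stopping from EMG and Frontal Beta Bursts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-trial analysis of human action-stopping in the
    stop-signal task. Implements EMG burst landmarking and the CancelTime
    estimate of stopping latency, generalized-eigendecomposition (GED)
    derivation of a right-frontal spatial filter, Hilbert-envelope beta-burst
    detection (BurstTime, burst probability, burst width), behavioral
    stop-signal measures including integration-method SSRT, and the
    trial-level (repeated-measures correlation) and between-subject statistics
    linking burst timing to stopping latency. A synthetic-cohort generator
    emulates the assumed data-generating structure (ex-Gaussian go process,
    staircased stop-signal delays, partial EMG bursts truncated at the
    cancellation time, right-frontal beta-burst EEG source, and an optional
    TMS condition), so the full pipeline is testable end to end without any
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'montage.R'
    'synthgen-race.R'
    'synthgen-emg.R'
    'synthgen-eeg.R'
    'synthgen-cohort.R'
    'behavior.R'
    'emg.R'
    'spectral.R'
    'gedfilter.R'
    'betaburst.R'
    'stats.R'
    'pipeline.R'
    'utils.R'
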