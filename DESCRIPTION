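Package: hybridbci
Title: Simulation and Decoding for a Hybrid EEG/EOG Brain-Computer
    Interface with Shared Robot Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico pipeline for a hybrid brain-computer interface
    that combines sensorimotor-rhythm event-related desynchronization
    (SMR-ERD) decoding of EEG with horizontal-oculoversion (HOV) detection
    on bipolar EOG to drive a five-state shared-control machine for
    robot-assisted drinking and pouring tasks.  Includes a synthetic
    participant signal generator (1 kHz EEG/EOG with parameterised SMR
    depth, reaction latencies and pre-activation behaviour), surface
    Laplacian and Butterworth preprocessing, Burg autoregressive band-power
    estimation, calibration of reference values and detection thresholds,
    online activation detection, per-trial feasibility metrics (time to
    initialize, pre-cue activation, normalized open/close time) and the
    nonparametric repeated-measures statistics used to compare devices and
    control modes (Shapiro-Wilk, Friedman, Wilcoxon signed-rank with Pratt
    zero handling, Holm-Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
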