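Package: reachpe
Title: Visuomotor Prediction-Error EEG Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for visuomotor rotation EEG
    experiments in which an instructed-strategy condition is contrasted with a
    post-adaptation condition to isolate visuomotor prediction errors. Covers
    the experimental task geometry and pseudorandomized trial scheduling,
    synthetic stylus-trajectory and 64-channel EEG generation with known
    ground-truth effects, reach kinematics and kinematic trial rejection,
    EEG preprocessing (zero-phase filtering, average reference, epoching,
    baseline correction, amplitude screening, independent-component artifact
    scoring), spherical-spline surface-Laplacian current source density,
    Morlet-wavelet event-related spectral perturbations with median trial
    aggregation and decibel baseline normalization, ERP region-of-interest
    peak-to-peak scoring (visual N1, feedback-related negativity), and binned
    Wilcoxon signed-rank statistics with Benjamini-Hochberg false discovery
    rate control and scalp z-maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
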