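Package: perisacc
Title: Decoding Saccade Timing and Direction from Peri-Saccadic V1 Local
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline quantifying the eye-movement information
    carried by peri-saccadic local field potentials (LFPs) recorded in
    primary visual cortex. Provides a synthetic trial-set generator with
    direction-tuned saccade-locked LFP templates in 1/f background noise,
    velocity-threshold saccade detection, fixation-aligned epoch
    extraction, linear max-margin (SVM) classification of saccade versus
    fixation epochs scored by signed hyperplane distances (s-values) under
    leave-one-out cross-validation, criterion-free ROC/AUC, a temporal
    train/test window sweep that estimates fixation onset to millisecond
    precision, saccade-direction decoding with circular error statistics,
    a permutation test on LFP waveform-shape correlations, and channel
    pooling with sequential-addition optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
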