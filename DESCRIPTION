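Package: myofeat
Title: Nonlinear Time-Domain Features for Myoelectric Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for surface electromyogram (sEMG) movement classification
    built around two nonlinear time-domain features, the log mean absolute
    value (LMAV) and the nonlinear scaled value (NSV). Implements the classical
    time-domain EMG feature inventory and the standard feature-set baselines,
    uncorrelated linear discriminant analysis (ULDA) reduction, the RES cluster
    separability index, greedy forward feature selection with a minimum-gain
    stopping rule, trial-wise cross-validated evaluation with LDA/SVM/KNN
    classifiers, window-size and signal-to-noise-ratio robustness sweeps, and a
    synthetic multi-movement EMG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
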