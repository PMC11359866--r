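Package: uwbfall
Title: UWB Radar Human Fall Classification with SE-RCNet and Adaptive
    Weighted Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying human falls and daily
    activities from ultra-wideband (UWB) impulse radar echoes. Includes a
    seeded point-scatterer echo simulator (10 action classes: 5 daily
    activities, 5 fall variants), three-map preprocessing (moving-target
    indication via a three-pulse canceller, Hilbert analytic envelope,
    short-time Fourier transform and slow-time FFT yielding range-time,
    time-Doppler and range-Doppler magnitude maps), a
    squeeze-and-excitation residual concatenate network (SE-RCNet)
    classifier implemented from first principles with Armadillo-backed
    convolution kernels, confidence-based decision-level fusion, and
    adaptive weighted fusion that scales each map's per-sample softmax
    confidence by its validation accuracy. Evaluation utilities provide
    stratified 6:2:2 splits, stratified k-fold cross-validation,
    confusion matrices and macro-averaged precision/recall/F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
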