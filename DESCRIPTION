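Package: afmsdc
Title: Multi-Scale Dilated Convolutional Networks for Atrial
    Fibrillation Detection from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, analyzes and trains one-dimensional convolutional
    neural networks for atrial fibrillation detection from single-lead
    electrocardiograms. The core building block is the multi-scale
    dilated convolution (MSDC) block: parallel dilated convolution
    branches with differing kernel sizes and dilation factors merged on
    the channel axis, replacing the residual block of a 1D ResNet at a
    fraction of the parameter count while preserving the receptive
    field. Includes an exact static architecture analyzer (tap-union
    receptive fields and parameter counts per branch tuple), a
    self-contained training engine (dilated convolutions via
    RcppArmadillo, batch normalization, Adam, early stopping), a
    synthetic single-lead ECG rhythm simulator for desk-scale
    end-to-end testing, WFDB record windowing with rhythm-purity
    checks, 8:1:1 dataset splitting, and the standard evaluation
    metrics (sensitivity, specificity, per-class and macro F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
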