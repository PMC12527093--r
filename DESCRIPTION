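Package: lmcsleep
Title: Lightweight Multi-Channel Sleep Staging from Wavelet Scalograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic sleep staging for multi-channel polysomnography.
    Converts 30-second EEG/EOG epochs into Morlet continuous-wavelet-transform
    scalograms (32 scales, median-downsampled to 200 time points) and
    classifies them into the five AASM stages (W, N1, N2, N3, REM) with a
    lightweight convolutional network: a multi-scale dilated-convolution stem,
    a depthwise-separable residual (ResNet18-style) body, a convolutional
    block attention module, and a softmax head. Includes a minimal EDF/EDF+
    reader and writer for Sleep-EDF-style recordings, a synthetic PSG
    generator with stage-dependent spectral signatures, weighted
    cross-entropy training with Adam, early stopping and subject-wise k-fold
    cross-validation, and confusion-matrix evaluation (per-class
    precision/recall/F1, accuracy, macro-F1, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
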