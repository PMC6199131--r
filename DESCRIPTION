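Package: neuroconf
Title: Race-Model Decision Confidence and Single-Trial EEG-Informed fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying perceptual decision confidence with a
    two-accumulator race model (balance-of-evidence confidence, grid-search
    maximum-likelihood fitting via a Kolmogorov-Smirnov likelihood),
    single-trial sliding-window EEG discriminant analysis (leave-one-out ROC
    Az, permutation significance, forward models, out-of-sample confidence
    component amplitudes), prestimulus alpha-power controls (multitaper
    spectral estimation), behavioural and mediation statistics, and
    EEG-informed fMRI general linear models with amplitude-permutation
    cluster thresholding, psychophysiological-interaction designs and
    percent-signal-change extraction. Includes synthetic-data generators with
    known ground truth (behaviour, ratings, multichannel EEG epochs with a
    planted confidence component, 4D BOLD volumes) so every stage of the
    pipeline can be validated without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
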