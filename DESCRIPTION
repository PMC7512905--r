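Package: eegentropy
Title: Entropy-Based Decoding of Auditory Attention from Single-Trial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying auditory object-specific attention states
    (Rest, AOA1, AOA2) from single-trial multichannel EEG. Implements
    wavelet-based preprocessing (linear detrending and 9-level db4 denoising),
    four nonlinear complexity features (approximate entropy, sample entropy,
    composite multiscale entropy and fuzzy entropy, plus permutation entropy),
    a statistical comparison cascade (Bartlett, Shapiro-Wilk, ANOVA or
    Kruskal-Wallis dispatch with Bonferroni-corrected pairwise comparisons),
    and LDA- and SVM-based three-class attention classifiers evaluated under
    leave-one-out cross-validation with a chi-squared test against chance
    level. A seeded synthetic-EEG generator with condition-dependent signal
    complexity makes the whole pipeline testable without access to recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
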