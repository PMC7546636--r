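Package: rubeoscan
Title: Contactless Screening for Diabetic Neuropathy from Facial Video Pulse Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening diabetic neuropathy from short face videos.
    Pulse-driven facial color variation that is invisible to the naked eye is
    amplified with Eulerian video magnification, summarised as a normalized
    spatio-temporal tensor profile of the difference between the reddest and
    palest facial patches, and characterised through the empirical spectral
    density of largest eigenvalues of windowed covariance matrices. The right
    tail of that density is fitted with generalized Pareto, Gamma
    (a Tracy-Widom surrogate) and power-law models; the sign of the Pareto
    tail index separates scale-free (control-like) from random
    (neuropathy-like) dynamics. Subjects are classified with a cross-validated
    optimal weighted ensemble of base learners fused by majority voting over
    video segments, and a synthetic-data generator emulates both feature-level
    eigenvalue samples and pulse-modulated face videos for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
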