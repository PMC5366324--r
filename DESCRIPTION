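Package: eegnaming
Title: Predicting Picture-Naming Accuracy in Aphasia from Single-Trial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Within-participant prediction of picture-naming outcomes from
    EEG spectral features. Provides a synthetic multi-session EEG generator
    with planted, participant-specific links between band-limited amplitude
    and naming accuracy; order-40 Burg autoregressive spectral estimation on
    1000-ms sliding windows reduced to 4-Hz band amplitudes; an elastic-net
    solver (coordinate descent over both L1 and L2 penalties with embedded
    cross-validation); session-based train/test evaluation by Pearson
    correlation with selected-feature degrees of freedom; channel-by-band
    correlation topographies; and behavioral response tabulation with
    repeated-measures ANOVA, Mauchly's sphericity test and the
    Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
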