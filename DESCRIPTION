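Package: salivaraman
Title: Raman Micro-Spectroscopy of Saliva for Obstructive Sleep Apnea Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric pipeline for label-free screening of obstructive
    sleep apnea syndrome (OSAS) from dried-drop saliva Raman spectra.
    Provides readers and writers for per-acquisition spectra and clinical
    covariate tables; spectral preprocessing (signal-to-noise quality gate,
    iterative masked polynomial baseline subtraction, reference-peak axis
    alignment, common-grid resampling, normalization, per-subject replicate
    averaging); PCA-LDA classification of OSAS versus control subjects with
    leave-one-out cross-validation, principal-component count selection,
    confusion metrics and ROC analysis of the canonical-variable scores; the
    lactic-acid 920 cm-1 peak-area biomarker with its univariate, stratified,
    correlation and linear-model statistics; and a synthetic cohort generator
    that emulates replicate saliva spectra and clinical covariates with a
    configurable peak library, so every stage of the pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    lmtest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
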