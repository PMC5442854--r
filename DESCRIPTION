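Package: reims
Title: Rapid Evaporative Ionisation Mass Spectrometry Tissue Classification
Version: 0.1.0
Authors@R:
    person("REIMS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating lipidomic tissue-recognition
    models from rapid evaporative ionisation mass spectrometry (REIMS)
    profile spectra, as produced by electrosurgical ("iKnife") dissection.
    Provides a labelled synthetic-spectrum generator, spectral preprocessing
    (binning, background subtraction, lock-mass recalibration, burn
    averaging, profile alignment, peak picking, median-fold-change
    normalisation), PCA-LDA classification with Mahalanobis closest-class
    recognition and outlier gating, leave-one-patient-out cross-validation,
    a Mann-Whitney/Benjamini-Yekutieli univariate marker screen, and
    theoretical monoisotopic m/z calculation for negative-mode
    glycerophospholipid and triglyceride ions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
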