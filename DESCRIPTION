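Package: ramanstage
Title: Staging Proliferating Human Hepatocytes from Single-Cell Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for staging primary human hepatocytes (PHH)
    and their proliferating, progressively progenitor-like derivatives
    (ProliHHs, passages P1 and P4) from single-cell Raman spectra of the
    fingerprint region (300-1800 cm^-1). Provides spectral preprocessing
    (cosmic-ray despiking, asymmetric-least-squares baseline correction, area
    normalization), band-area semi-quantification with Student's t-test group
    comparisons, PCA and Fisher linear discriminant analysis with
    discriminant-loading ranking, and a two-layer stacked classifier (KNN,
    PCA-LDA, PLS-DA, linear and RBF SVM, random forest base learners combined
    by a gradient-boosting meta-learner) evaluated through
    prediction-by-reference confusion matrices. Includes a synthetic
    single-cell spectrum generator that emulates the class structure of the
    hepatocyte study so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    pracma,
    caret,
    e1071,
    ranger,
    xgboost,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    MASS
Config/testthat/edition: 3
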