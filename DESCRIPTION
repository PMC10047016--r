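Package: cemradial
Title: Radial Intensity Histogram Analysis of Contrast-Enhanced Mammography Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of paired low-energy ("density") and
    recombined ("contrast") contrast-enhanced mammography (CEM) lesion images.
    Computes area-normalized radial distributions of intensity in concentric
    bands around the contour-derived center of mass of a finding, classifies
    malignant versus benign (and invasive versus non-invasive) findings with a
    ridge-penalized linear discriminant analysis under repeated stratified
    cross-validation, and combines cross-validated imaging scores with clinical
    covariates in logistic and AUC-ROC models. Includes a fully synthetic CEM
    cohort generator (images, contour annotations, clinical metadata) so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    glmnet
Config/testthat/edition: 3
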