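Package: sdaecadx
Title: Stacked Denoising Autoencoder CADx for Ultrasound and CT Lesion
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) toolkit for differentiating
    benign from malignant lesions in 2D ultrasound regions of interest and
    multi-slice CT nodule stacks. Implements a stacked denoising autoencoder
    (SDAE) classifier with greedy layer-wise pretraining, auxiliary geometry
    inputs and softmax fine-tuning; conventional texture baselines built on
    the ranklet transform, sub-band decomposition and gray-level
    co-occurrence matrix (GLCM) Haralick statistics with bootstrap feature
    selection and SVM classification; clinical morphological features from
    lesion masks; slice-selection strategies with nodule-level majority
    voting; and a repeated, stratified 10-fold cross-validation harness
    reporting six diagnostic metrics, Bland-Altman agreement statistics and
    two-sample t-tests. A seeded synthetic-image generator produces
    speckle-corrupted ultrasound-like lesions and CT-like nodule slice
    stacks with class-dependent morphology so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
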