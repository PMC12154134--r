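Package: cystratify
Title: Cyst-Level Malignancy Risk Stratification for IPMN from T2W MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for stratifying malignancy risk of intraductal
    papillary mucinous neoplasms (IPMNs) from cyst-level T2-weighted MRI
    features. Provides a seeded synthetic multi-center cohort generator,
    isotropic resampling and bias-field preprocessing, a six-family 2D/3D
    radiomic texture feature bank (raw, gray filters, gradient, Laws energy,
    Haralick GLCM, CoLlAGe), Spearman redundancy filtering with stability-based
    mRMR feature selection, leave-center-out random-forest classification, a
    reduced-scale 3D convolutional probability stage, decision-level
    radiomics-deep-learning probability fusion, segmentation and rater
    agreement statistics (Dice, HD95, weighted kappa, Cochran's Q), and
    image-quality indicator profiling with 2D embedding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    randomForest,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
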