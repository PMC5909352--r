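Package: dcemcs
Title: Multiple Classifier System for Breast Lesion Classification on DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies breast lesions as benign or malignant on dynamic
    contrast-enhanced MRI (DCE-MRI) by combining two feature channels: a
    Gaussian naive-Bayes classifier applied voxel by voxel to kinetic
    (dynamic) features, and a decision tree applied to lesion-level shape
    (morphological) features, fused by a weighted probability rule with a
    data-driven mixing coefficient. Includes fully automatic lesion
    segmentation from the 4D series (sum-of-intensity-differences parametric
    map, Otsu thresholding, morphological cleanup, kinetic suspicious-voxel
    rules), the retained shape and kinetic feature formulas,
    correlation-based and consistency-based feature selection, and a
    synthetic DCE-MRI phantom generator so the whole pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
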