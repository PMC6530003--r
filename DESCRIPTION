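Package: nodetex
Title: CT Texture Analysis of Mediastinal Lymph Nodes: Phantom Simulation,
    First-Order Features, and Diagnostic Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-dimensional lymph-node CT phantoms with
    benign/malignant texture structure, extracts first-order histogram and
    shape features (mean attenuation, standard deviation, size-normalized
    standard deviation, skewness, kurtosis, entropy, percentiles,
    circularity, compactness, roundness) from image/mask pairs after
    calcification exclusion, and evaluates diagnostic accuracy with group
    comparisons, ROC/AUC with Hanley-McNeil standard errors, combined
    PET/CT positivity criteria, and single-split (stump) CART analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    optparse
Config/testthat/edition: 3
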