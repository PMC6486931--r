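Package: mpcad
Title: Multiparametric PET/MRI Computer-Aided Segmentation and Diagnosis of Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-wise random-forest segmentation and lesion-level
    benign/malignant classification pipeline for co-registered multiparametric
    breast imaging studies (DCE-MRI time series, high-resolution pre/peak/post
    contrast MRI, DWI/ADC and FDG-PET). Implements the 62-feature per-voxel
    intensity descriptor, characteristic-kinetic-curve extraction by fuzzy
    c-means, a six-parameter sigmoid-times-exponential contrast-enhancement
    model with curve summaries, spatial and spatio-temporal grey-level
    co-occurrence (Haralick) texture features, shape descriptors, Gini and
    minimum-redundancy-maximum-relevance feature ranking, and leave-one-out
    cross-validation harnesses for both stages. Ships a seeded synthetic
    multiparametric phantom generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    minpack.lm,
    randomForest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    e1071,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
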