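Package: voltexture
Title: Volumetric GLCM Texture Analysis and Lesion Classification for
    Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies clinically significant prostate cancer from paired
    T2-weighted/ADC volumetric lesion patches using three-dimensional
    gray-level co-occurrence matrices (GLCMs). Provides a 13-direction 3D
    GLCM extractor over 64 gray levels, a compact convolutional network
    trained on the 26-channel GLCM stack, a 104-feature Haralick
    random-forest baseline, a PI-RADS >= 4 rule baseline, and a paired
    evaluation suite with bootstrap AUC confidence intervals, Youden
    operating points, Wald intervals, and DeLong and McNemar tests,
    including clinical subgroup reports. A texture-phantom generator
    produces fully synthetic labeled cohorts so the entire pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    readr,
    randomForest,
    RNifti,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
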