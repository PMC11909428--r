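Package: retilab
Title: Cross-Device Validation of Retinal OCT Layer Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic spectral-domain OCT phantoms with known internal limiting
    membrane (ILM), retinal pigment epithelium (RPE) and Bruch's membrane (BM)
    geometry under two emulated device profiles; compact trainable encoder-decoder
    and dilated-convolution segmentation networks; percentile-based boundary
    extraction from multi-pixel label masks; and an evaluation battery (exclusion-rule
    MAE/MSE, volumetric Dice, neurosensory-retina and RPE-drusen-complex volumes,
    Bland-Altman limits of agreement, intergrader RMSE, en face thickness maps) for
    exercising cross-device generalization experiments at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    RNifti,
    png,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
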