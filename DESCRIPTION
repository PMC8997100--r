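Package: maaspenn
Title: MaasPenn Reproducibility Score for CT Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the reproducibility of CT-based handcrafted radiomic
    features across scans acquired with different acquisition and
    reconstruction settings. Encodes pairwise differences in eight
    acquisition parameters (vendor, model, tube current, exposure, exposure
    time, slice thickness, pixel spacing, convolution kernel) into [0, 1]
    agreement values, measures per-feature reproducibility with Lin's
    concordance correlation coefficient over phantom volume-of-interest
    grids, assesses harmonizability with empirical-Bayes (ComBat) batch
    adjustment and voxel-size resampling, fits a regression random forest
    of percent-reproducible features on the encoded parameters, and derives
    the importance-weighted MaasPenn score with ROC-selected decision
    cut-offs for prospective scan screening and retrospective signature
    audits. Includes a synthetic phantom-study generator with known ground
    truth for validation without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
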