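#' The handcrafted radiomic feature registry
#'
#' The 91 original-image handcrafted radiomic features (HRFs) used by the
#' reproducibility analysis: 18 first-order intensity statistics and 73
#' texture features over five matrices (22 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM). Names follow the PyRadiomics `original_<family>_<name>`
#' convention; the feature mathematics themselves are delegated to an
#' external extractor (see [extract_features()]).
#'
#' @return Tibble with columns `feature` and `family`, 91 rows.
#' @export
#' @examples
#' dplyr::count(feature_registry(), family)
feature_registry <- function() {
  fams <- list(
    firstorder = c(
      "10Percentile", "90Percentile", "Energy", "Entropy",
      "InterquartileRange", "Kurtosis", "Maximum", "Mean",
      "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
      "TotalEnergy", "Uniformity", "Variance"),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
      "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
      "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy",
      "SumSquares"),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
  reg <- dplyr::bind_rows(purrr::imap(fams, function(nm, fam) {
    tibble::tibble(feature = paste("original", fam, nm, sep = "_"),
                   family = fam)
  }))
  counts <- c(firstorder = 18L, glcm = 22L, glrlm = 16L, glszm = 16L,
              gldm = 14L, ngtdm = 5L)
  got <- table(factor(reg$family, levels = names(counts)))
  stopifnot(identical(as.integer(got), unname(counts)),
            nrow(reg) == 91L, !anyDuplicated(reg$feature))
  reg
}

#' The three image-processing arms
#'
#' Features are extracted three times per scan: from the original voxel
#' grid, after resampling every scan to the dataset's median voxel size
#' (0.68 x 0.68 x 1.5 mm) and after resampling to the largest voxel size
#' (0.98 x 0.98 x 3.75 mm), in both cases with cosine-windowed-sinc
#' interpolation. Intensities are discretised with a fixed 25 HU bin width
#' in every arm.
#'
#' @return Tibble with columns `arm`, `target_x`, `target_y`, `target_z`
#'   (mm, `NA` = keep native grid), `interpolator`, `bin_width` (HU).
#' @export
processing_arms <- function() {
  tibble::tibble(
    arm = c("original", "median_resample", "largest_resample"),
    target_x = c(NA, 0.68, 0.98),
    target_y = c(NA, 0.68, 0.98),
    target_z = c(NA, 1.5, 3.75),
    interpolator = c(NA, "cosine_windowed_sinc", "cosine_windowed_sinc"),
    bin_width = 25
  )
}

#' Names of the feature columns of a feature table
#'
#' @param tbl A feature table (tibble with `scan_id`, `arm`, `voi_id` plus
#'   one column per registry feature).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(tbl) {
  setdiff(names(tbl), c("scan_id", "arm", "voi_id"))
}

#' Read / write a feature table
#'
#' Feature tables are stored as CSV with header
#' `scan_id,arm,voi_id,<feature columns>`, one row per VOI.
#'
#' @param path File path.
#' @return `read_feature_table()`: a tibble; `write_feature_table()`: the
#'   input, invisibly.
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("scan_id", "arm", "voi_id") %in% names(tbl))) {
    rlang::abort("feature table needs scan_id, arm, voi_id columns")
  }
  tbl
}

#' @rdname read_feature_table
#' @param tbl Feature table to write.
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(tbl)
}

# samples x features numeric matrix from a single-scan feature table,
# rows ordered by voi_id
feature_matrix <- function(tbl) {
  tbl <- tbl[order(tbl$voi_id), ]
  m <- as.matrix(tbl[, feature_cols(tbl), drop = FALSE])
  rownames(m) <- tbl$voi_id
  m
}
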