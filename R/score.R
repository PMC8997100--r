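#' Compute the MaasPenn reproducibility score for encoded pairs
#'
#' The MaasPenn score of a scan pair is the weighted sum of its encoded
#' parameter agreement values over the retained parameters,
#' \eqn{\mathrm{score} = \sum_p w_p\, e_p}, with the published weights
#' (kernel 0.48, slice thickness 0.33, pixel spacing 0.19) by default.
#' Because weights sum to 1 and each encoding lies in \[0, 1\], the score
#' lies in \[0, 1\]; it equals 1 exactly when all retained parameters
#' agree, and is monotone non-decreasing in each component.
#'
#' @param encodings Pair-encoding tibble from [encode_pairs()] (any data
#'   frame holding the retained parameter columns).
#' @param weights A `maaspenn_weights` vector ([published_weights()] by
#'   default, or [derive_weights()] output).
#' @return The input tibble with a `score` column appended.
#' @export
#' @examples
#' meta <- scan_metadata(data.frame(
#'   scan_id = c("s1", "s2"), vendor = "GE", model = "M1",
#'   tube_current = 200, exposure = 100, exposure_time = 500,
#'   slice_thickness = c(1.5, 3), pixel_spacing = 0.68,
#'   kernel = c("SOFT", "SOFT")))
#' maaspenn_score(encode_pairs(meta))
maaspenn_score <- function(encodings, weights = published_weights()) {
  missing_cols <- setdiff(names(weights), names(encodings))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("encodings lack retained parameter column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  vals <- as.matrix(encodings[, names(weights), drop = FALSE])
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    rlang::abort("encoded values must lie in [0, 1] without NAs")
  }
  encodings$score <- as.numeric(vals %*% as.numeric(weights))
  encodings
}

#' Spearman correlation between score and outcome
#'
#' Rank correlation between the MaasPenn score and the percentage of
#' reproducible features across scenarios.
#'
#' @param scores,outcomes Numeric vectors of equal length >= 3.
#' @return Spearman's rho in \[-1, 1\]; `NA` when either input is constant.
#' @export
score_outcome_correlation <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    rlang::abort("scores and outcomes lengths differ")
  }
  if (length(scores) < 3) rlang::abort("need at least 3 pairs")
  if (stats::sd(scores) == 0 || stats::sd(outcomes) == 0) return(NA_real_)
  stats::cor(scores, outcomes, method = "spearman")
}
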