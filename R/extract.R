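#' Extract handcrafted radiomic features over a VOI grid
#'
#' Contract wrapper around a delegated feature extractor. The feature
#' mathematics (the 91 registry HRFs) are computed by `extractor`, a
#' function `function(voxels, spacing, bin_width)` returning a named numeric
#' vector covering every registry feature — typically a bridge to
#' PyRadiomics, which defined the registry. This wrapper owns everything
#' around it: mapping each VOI box from physical mm to voxel index ranges
#' (floor the start, ceil the end, half-open), applying the arm's 25 HU
#' discretisation bin width, validating the output against the registry and
#' collecting per-VOI failures. No other preprocessing is applied.
#'
#' @param img 3-d HU array (optionally with `spacing`/`origin` attributes).
#' @param grid A [build_voi_grid()] tibble.
#' @param arm One row of [processing_arms()] (or an arm name).
#' @param extractor The delegated feature function; the packaged
#'   [demo_extractor()] is a deterministic placeholder for pipeline testing
#'   only, not a radiomics implementation.
#' @param registry Feature registry tibble (default [feature_registry()]).
#' @param scan_id Scan identifier recorded in the output.
#' @param spacing,origin Geometry overrides (mm) if not carried as
#'   attributes of `img`.
#' @return Feature table tibble (`scan_id`, `arm`, `voi_id`, 91 feature
#'   columns), one row per VOI. VOIs whose extraction failed are reported
#'   in a single error listing the VOI indices.
#' @export
extract_features <- function(img, grid, arm = "original",
                             extractor = demo_extractor,
                             registry = feature_registry(),
                             scan_id = "scan",
                             spacing = attr(img, "spacing"),
                             origin = attr(img, "origin") %||% c(0, 0, 0)) {
  if (is.character(arm)) {
    arms <- processing_arms()
    arm <- arms[arms$arm == arm, ]
    if (nrow(arm) != 1) rlang::abort("unknown processing arm")
  }
  if (is.null(spacing)) rlang::abort("voxel spacing metadata is required")
  d <- base::dim(img)

  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    b <- grid[i, ]
    # physical mm -> 0-based half-open voxel index range
    i0 <- floor((c(b$x0, b$y0, b$z0) - origin) / spacing)
    i1 <- ceiling((c(b$x1, b$y1, b$z1) - origin) / spacing)
    i0 <- pmax(i0, 0); i1 <- pmin(i1, d)
    if (any(i1 <= i0)) return(simpleError("VOI outside image"))
    vox <- img[(i0[1] + 1):i1[1], (i0[2] + 1):i1[2], (i0[3] + 1):i1[3],
               drop = FALSE]
    tryCatch(extractor(vox, spacing = spacing, bin_width = arm$bin_width),
             error = identity)
  })

  failed <- purrr::map_lgl(res, inherits, "error")
  if (any(failed)) {
    msgs <- purrr::map_chr(res[failed], conditionMessage)
    rlang::abort(c("feature extraction failed for VOI(s):",
                   stats::setNames(paste0("voi ", grid$voi_id[failed], ": ",
                                          msgs),
                                   rep("x", sum(failed)))))
  }
  vals <- purrr::map(res, function(v) {
    miss <- setdiff(registry$feature, names(v))
    if (length(miss) > 0) {
      rlang::abort(paste0("extractor output missing feature(s): ",
                          paste(utils::head(miss, 3), collapse = ", ")))
    }
    v[registry$feature]
  })
  m <- do.call(rbind, vals)
  if (any(!is.finite(m))) rlang::abort("non-finite feature value(s)")
  out <- tibble::as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble::tibble(scan_id = scan_id, arm = arm$arm,
                                  voi_id = grid$voi_id), out)
}

#' Deterministic placeholder extractor
#'
#' Computes a small set of intensity summary statistics of the 25-HU-binned
#' VOI and maps them deterministically onto the 91 registry feature names.
#' This exists so the pipeline around the extractor contract can be
#' exercised end-to-end without PyRadiomics; its values are *not* the
#' registry features' definitions and must not be interpreted as radiomics.
#'
#' @param voxels 3-d numeric array (HU).
#' @param spacing Voxel spacing, mm.
#' @param bin_width Discretisation bin width, HU.
#' @return Named numeric vector over [feature_registry()]`$feature`.
#' @export
demo_extractor <- function(voxels, spacing, bin_width = 25) {
  v <- as.numeric(voxels)
  b <- floor(v / bin_width)  # discretised levels
  p <- tabulate(b - min(b) + 1L)
  p <- p[p > 0] / length(b)
  stats_base <- c(
    mean(v), stats::median(v), sqrt(mean(v^2)), sum(v^2) * prod(spacing),
    stats::sd(v), stats::quantile(v, 0.1, names = FALSE),
    stats::quantile(v, 0.9, names = FALSE), min(v), max(v),
    -sum(p * log2(p)), sum(p^2), mean(abs(v - mean(v)))
  )
  reg <- feature_registry()$feature
  k <- seq_along(reg)
  vals <- stats_base[(k - 1L) %% length(stats_base) + 1L] *
    (1 + 0.01 * ((k - 1L) %/% length(stats_base)))
  stats::setNames(vals, reg)
}
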