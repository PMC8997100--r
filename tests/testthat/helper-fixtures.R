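# Small in-code fixtures shared across the suite.

# metadata builder with sensible defaults; override any field per scan
make_meta <- function(n = 2, vendor = "GE", model = "LightSpeed16",
                      tube_current = 200, exposure = 100,
                      exposure_time = 500, slice_thickness = 1.5,
                      pixel_spacing = 0.68, kernel = "STANDARD",
                      scan_id = sprintf("s%02d", seq_len(n))) {
  scan_metadata(tibble::tibble(
    scan_id = scan_id, vendor = vendor, model = model,
    tube_current = tube_current, exposure = exposure,
    exposure_time = exposure_time, slice_thickness = slice_thickness,
    pixel_spacing = pixel_spacing, kernel = kernel))
}

# tiny feature table: n_voi VOIs x given feature columns
make_table <- function(values, scan_id = "s01", arm = "original",
                       features = paste0("f", seq_len(ncol(values)))) {
  colnames(values) <- features
  dplyr::bind_cols(
    tibble::tibble(scan_id = scan_id, arm = arm,
                   voi_id = seq_len(nrow(values))),
    tibble::as_tibble(as.data.frame(values)))
}

# brute-force Lin CCC straight from the moment definition
brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2) / n
  syy <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sxx + syy + (mx - my)^2)
}

# exhaustive pairwise-concordance AUC (ties worth 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
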