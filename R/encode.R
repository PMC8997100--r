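#' Enumerate all unordered scan pairs
#'
#' Every unordered pair of distinct scans is one reproducibility scenario.
#' Pairs are canonically ordered (lexicographically smaller scan id first)
#' and each appears exactly once; `pair_id` is `"<a>:<b>"`.
#'
#' @param meta A `scan_metadata` tibble (or anything with a `scan_id`
#'   column), or a character vector of scan ids.
#' @return Tibble with columns `pair_id`, `scan_a`, `scan_b`; `choose(n, 2)`
#'   rows.
#' @export
#' @examples
#' enumerate_pairs(c("s1", "s2", "s3"))
enumerate_pairs <- function(meta) {
  ids <- if (is.character(meta)) meta else as.character(meta$scan_id)
  if (anyDuplicated(ids)) rlang::abort("duplicate scan_id(s)")
  n <- length(ids)
  if (n < 2) rlang::abort("need at least 2 scans to form pairs")
  idx <- utils::combn(n, 2L)
  a <- ids[idx[1L, ]]
  b <- ids[idx[2L, ]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tibble::tibble(pair_id = paste(a, b, sep = ":"), scan_a = a, scan_b = b)
}

#' Kernel agreement value for a scan pair
#'
#' Two convolution kernels are compared through their schema ranks (limiting
#' frequency order): the agreement value is `min(rank) / max(rank)`, so
#' identical or equally ranked kernels score 1 and increasingly dissimilar
#' sharpness scores approach 0.
#'
#' @param k1,k2 Kernel names (vectorised).
#' @param schema A [kernel_schema()] covering every kernel used.
#' @return Numeric in (0, 1].
#' @export
#' @examples
#' sch <- kernel_schema(data.frame(kernel = c("SOFT", "BONE"), rank = c(2, 4)))
#' kernel_value("SOFT", "BONE", sch)
kernel_value <- function(k1, k2, schema) {
  schema <- kernel_schema(schema)
  r1 <- schema$rank[match(k1, schema$kernel)]
  r2 <- schema$rank[match(k2, schema$kernel)]
  unknown <- unique(c(k1[is.na(r1)], k2[is.na(r2)]))
  if (length(unknown) > 0) {
    rlang::abort(paste0("kernel(s) not in schema: ",
                        paste(unknown, collapse = ", ")))
  }
  pmin(r1, r2) / pmax(r1, r2)
}

#' Encode the parameter agreement of one scan pair
#'
#' Maps each of the eight acquisition parameters of an unordered scan pair
#' to an agreement value in \[0, 1\]: vendor and model are binary (1 iff
#' equal); tube current, exposure, exposure time, slice thickness and pixel
#' spacing take `min / max` across the pair; the convolution kernel takes
#' the rank ratio of [kernel_value()]. The encoding is symmetric in the two
#' scans and equals 1 componentwise iff the parameters agree exactly.
#'
#' @param a,b Single-row data frames (or named lists) with the
#'   [scan_parameters()] fields.
#' @param schema A [kernel_schema()].
#' @return One-row tibble: `pair_id`, `scan_a`, `scan_b`, then the eight
#'   encoded parameter columns.
#' @export
encode_pair <- function(a, b, schema = default_kernel_schema()) {
  m <- scan_metadata(dplyr::bind_rows(tibble::as_tibble(a),
                                      tibble::as_tibble(b)))
  encode_pairs(m, schema = schema)
}

#' Encode all scan pairs of a dataset
#'
#' Applies [encode_pair()]'s rules to every unordered pair of scans (or to a
#' supplied pair list). Scans with a missing parameter make their pairs
#' unencodable: the default policy is a hard error, `on_missing = "drop"`
#' silently excludes the affected pairs and records how many were dropped in
#' the `dropped_pairs` attribute.
#'
#' @param meta A `scan_metadata` tibble.
#' @param schema A [kernel_schema()] covering every kernel in `meta`.
#' @param pairs Optional pair tibble from [enumerate_pairs()]; default all
#'   pairs.
#' @param on_missing `"error"` (default) or `"drop"`.
#' @return Tibble with one row per pair: `pair_id`, `scan_a`, `scan_b` and
#'   the eight encoded parameters, each in \[0, 1\].
#' @export
#' @examples
#' meta <- scan_metadata(data.frame(
#'   scan_id = c("s1", "s2"), vendor = c("GE", "GE"),
#'   model = c("M1", "M2"), tube_current = c(100, 200),
#'   exposure = c(100, 100), exposure_time = c(500, 500),
#'   slice_thickness = c(1.5, 3), pixel_spacing = c(0.68, 0.68),
#'   kernel = c("SOFT", "STANDARD")))
#' encode_pairs(meta)
encode_pairs <- function(meta, schema = default_kernel_schema(),
                         pairs = NULL,
                         on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  meta <- scan_metadata(meta)
  schema <- kernel_schema(schema)
  if (is.null(pairs)) pairs <- enumerate_pairs(meta)

  incomplete <- meta$scan_id[!stats::complete.cases(
    meta[, scan_parameters()])]
  n_dropped <- 0L
  if (length(incomplete) > 0) {
    if (on_missing == "error") {
      rlang::abort(c("scans with missing parameters (use on_missing = \"drop\" to exclude their pairs):",
                     stats::setNames(incomplete, rep("x", length(incomplete)))))
    }
    keep <- !(pairs$scan_a %in% incomplete | pairs$scan_b %in% incomplete)
    n_dropped <- sum(!keep)
    pairs <- pairs[keep, ]
  }

  ia <- match(pairs$scan_a, meta$scan_id)
  ib <- match(pairs$scan_b, meta$scan_id)
  if (anyNA(ia) || anyNA(ib)) rlang::abort("pair refers to unknown scan_id")

  out <- pairs
  out$vendor <- as.numeric(meta$vendor[ia] == meta$vendor[ib])
  out$model <- as.numeric(meta$model[ia] == meta$model[ib])
  for (p in numeric_parameters()) {
    va <- meta[[p]][ia]; vb <- meta[[p]][ib]
    out[[p]] <- pmin(va, vb) / pmax(va, vb)
  }
  out$kernel <- kernel_value(meta$kernel[ia], meta$kernel[ib], schema)
  attr(out, "dropped_pairs") <- n_dropped
  out
}
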