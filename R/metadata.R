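#' Acquisition metadata parameters used by the reproducibility analysis
#'
#' The eight CT acquisition/reconstruction parameters that drive the pairwise
#' encoding: hardware make (vendor, model), noise parameters (tube current,
#' exposure, exposure time) and resolution parameters (slice thickness, pixel
#' spacing, convolution kernel).
#'
#' @return Character vector of the eight parameter names, in canonical order.
#' @export
#' @examples
#' scan_parameters()
scan_parameters <- function() {
  c("vendor", "model", "tube_current", "exposure", "exposure_time",
    "slice_thickness", "pixel_spacing", "kernel")
}

numeric_parameters <- function() {
  c("tube_current", "exposure", "exposure_time", "slice_thickness",
    "pixel_spacing")
}

required_metadata_cols <- function() c("scan_id", scan_parameters())

# Column aliases matching the DICOM attribute names the fields come from.
dicom_aliases <- c(
  Manufacturer          = "vendor",
  ManufacturerModelName = "model",
  XRayTubeCurrent       = "tube_current",
  Exposure              = "exposure",
  ExposureTime          = "exposure_time",
  SliceThickness        = "slice_thickness",
  PixelSpacing          = "pixel_spacing",
  ConvolutionKernel     = "kernel",
  SeriesInstanceUID     = "scan_id"
)

#' Construct a scan metadata table
#'
#' Builds and validates a tibble of per-scan acquisition metadata. One row per
#' scan; numeric fields carry their native units (tube current mA, exposure
#' mAs, exposure time ms, slice thickness mm, pixel spacing mm). An
#' anisotropic in-plane pixel spacing should be averaged to a single scalar
#' before entry.
#'
#' @param x A data frame with columns `scan_id` plus [scan_parameters()]
#'   (DICOM-style column names such as `Manufacturer` or `SliceThickness`
#'   are accepted and renamed).
#' @return A validated tibble of class `scan_metadata`.
#' @seealso [read_scan_metadata()], [validate_scan_metadata()]
#' @export
scan_metadata <- function(x) {
  x <- tibble::as_tibble(x)
  hit <- intersect(names(dicom_aliases), names(x))
  if (length(hit) > 0) {
    names(x)[match(hit, names(x))] <- unname(dicom_aliases[hit])
  }
  missing_cols <- setdiff(required_metadata_cols(), names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("metadata is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- dplyr::select(x, dplyr::all_of(required_metadata_cols()),
                     dplyr::everything())
  x$scan_id <- as.character(x$scan_id)
  x$vendor <- as.character(x$vendor)
  x$model <- as.character(x$model)
  x$kernel <- as.character(x$kernel)
  for (p in numeric_parameters()) x[[p]] <- as.numeric(x[[p]])
  # 0 in a header means "not recorded" for the dose-related fields, never a
  # legitimate physical value: coerce to NA so the missing-data policy sees it.
  for (p in c("tube_current", "exposure", "exposure_time")) {
    zero <- !is.na(x[[p]]) & x[[p]] == 0
    x[[p]][zero] <- NA_real_
  }
  validate_scan_metadata(x)
  class(x) <- c("scan_metadata", class(x))
  x
}

#' Validate a scan metadata table
#'
#' Checks the structural invariants: unique scan ids and strictly positive
#' numeric parameters where present. Violations raise an error carrying a
#' per-scan problem report; missing values are reported by
#' [metadata_problems()] but are not an error here (the missing-data policy
#' is applied at encoding time).
#'
#' @param meta A data frame as accepted by [scan_metadata()].
#' @return `meta`, invisibly, if valid.
#' @export
validate_scan_metadata <- function(meta) {
  dup <- meta$scan_id[duplicated(meta$scan_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate scan_id(s): ",
                        paste(unique(dup), collapse = ", ")))
  }
  bad <- metadata_problems(meta)
  nonpos <- dplyr::filter(bad, .data$problem == "non-positive")
  if (nrow(nonpos) > 0) {
    msg <- paste0(nonpos$scan_id, ": ", nonpos$parameter, " = ",
                  nonpos$value)
    rlang::abort(c("non-positive numeric parameter value(s):",
                   stats::setNames(msg, rep("x", length(msg)))))
  }
  invisible(meta)
}

#' Report per-scan metadata problems
#'
#' @param meta A metadata data frame.
#' @return Tibble with columns `scan_id`, `parameter`, `problem`
#'   (`"missing"` or `"non-positive"`) and `value`; zero rows when clean.
#' @export
metadata_problems <- function(meta) {
  meta <- tibble::as_tibble(meta)
  rows <- purrr::map(scan_parameters(), function(p) {
    v <- meta[[p]]
    miss <- is.na(v)
    out <- tibble::tibble(scan_id = meta$scan_id[miss], parameter = p,
                          problem = "missing", value = NA_real_)
    if (p %in% numeric_parameters()) {
      np <- !is.na(v) & v <= 0
      out <- dplyr::bind_rows(out, tibble::tibble(
        scan_id = meta$scan_id[np], parameter = p,
        problem = "non-positive", value = v[np]))
    }
    out
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$scan_id, .data$parameter)
}

#' Read scan metadata from a delimited table
#'
#' Reads a CSV/TSV of per-scan acquisition metadata. Columns may use either
#' the canonical names (`scan_id`, `vendor`, ..., `kernel`) or the DICOM
#' attribute names they originate from (`Manufacturer`,
#' `ManufacturerModelName`, `XRayTubeCurrent`, `Exposure`, `ExposureTime`,
#' `SliceThickness`, `PixelSpacing`, `ConvolutionKernel`).
#'
#' @param path Path to a delimited text file.
#' @return A `scan_metadata` tibble, one row per scan.
#' @export
read_scan_metadata <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read: ", path))
  x <- readr::read_delim(path, show_col_types = FALSE,
                         delim = if (grepl("\\.tsv$", path)) "\t" else ",")
  scan_metadata(x)
}

#' Default convolution-kernel rank schema
#'
#' Convolution kernels are compared through a numeric rank that orders them
#' by limiting frequency (higher rank = sharper kernel). This default schema
#' is a stand-in that places common GE, Siemens, Philips and Canon/Toshiba
#' kernels into five sharpness tiers; site-specific schemas should be
#' supplied via [read_kernel_schema()] when the kernels in use are known.
#'
#' @return Tibble with columns `kernel` and `rank`, class `kernel_schema`.
#' @export
#' @examples
#' default_kernel_schema()
default_kernel_schema <- function() {
  schema <- tibble::tribble(
    ~kernel,      ~rank,
    # tier 1: smooth / soft tissue
    "SOFT",       1, "B20f", 1, "B20s", 1, "A",  1, "FC01", 1,
    # tier 2: standard body
    "STANDARD",   2, "B30f", 2, "B31f", 2, "B",  2, "FC08", 2,
    # tier 3: medium sharp / chest
    "CHEST",      3, "B45f", 3, "B46f", 3, "C",  3, "FC18", 3,
    # tier 4: sharp / bone
    "BONE",       4, "B60f", 4, "B64f", 4, "D",  4, "FC30", 4,
    # tier 5: ultra sharp / lung, edge
    "LUNG",       5, "EDGE", 5, "B70f", 5, "YC", 5, "FC50", 5
  )
  class(schema) <- c("kernel_schema", class(schema))
  schema
}

#' Read a kernel rank schema
#'
#' @param path CSV with columns `kernel,rank`, or a JSON object mapping
#'   kernel names to ranks.
#' @return A `kernel_schema` tibble.
#' @export
read_kernel_schema <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    schema <- tibble::tibble(kernel = names(m), rank = as.numeric(unlist(m)))
  } else {
    schema <- readr::read_csv(path, show_col_types = FALSE)
  }
  kernel_schema(schema)
}

#' Construct/validate a kernel schema
#'
#' @param x Data frame with columns `kernel` (character) and `rank`
#'   (strictly positive numeric).
#' @return A `kernel_schema` tibble.
#' @export
kernel_schema <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("kernel", "rank") %in% names(x))) {
    rlang::abort("kernel schema needs columns `kernel` and `rank`")
  }
  x$kernel <- as.character(x$kernel)
  x$rank <- as.numeric(x$rank)
  if (anyNA(x$rank) || any(x$rank <= 0)) {
    rlang::abort("kernel ranks must be strictly positive")
  }
  if (anyDuplicated(x$kernel)) {
    rlang::abort("duplicated kernel name(s) in schema")
  }
  if (!inherits(x, "kernel_schema")) class(x) <- c("kernel_schema", class(x))
  x
}
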