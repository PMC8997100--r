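#' Build the phantom VOI grid
#'
#' Subdivides each texture layer of the phantom into a centred in-plane grid
#' of equal cubic volumes of interest (VOIs). The default configuration —
#' 10 layers of 16 VOIs (a 4 x 4 in-plane arrangement), each
#' 2 x 2 x 2 cm — yields the 160 VOIs segmented per scan. Boxes are
#' axis-aligned, half-open intervals in physical mm, one layer per VOI slab
#' along z.
#'
#' @param layers Number of phantom texture layers (default 10).
#' @param vois_per_layer VOIs per layer; must be a perfect square for the
#'   square in-plane layout (default 16, i.e. 4 x 4).
#' @param voi_edge_cm VOI cube edge length in cm (default 2).
#' @param origin Numeric length-3, physical position (mm) of the image
#'   corner.
#' @param spacing Numeric length-3, voxel spacing in mm.
#' @param dim Integer length-3, image dimensions in voxels.
#' @return Tibble of class `voi_grid`: `voi_id`, `layer`, `row`, `col` and
#'   box bounds `x0,x1,y0,y1,z0,z1` (mm).
#' @export
#' @examples
#' g <- build_voi_grid(origin = c(0, 0, 0), spacing = c(0.68, 0.68, 1.5),
#'                     dim = c(180, 180, 140))
#' nrow(g)  # 160
build_voi_grid <- function(layers = 10, vois_per_layer = 16, voi_edge_cm = 2,
                           origin = c(0, 0, 0), spacing = c(1, 1, 1),
                           dim = NULL) {
  stopifnot(layers >= 1, vois_per_layer >= 1, voi_edge_cm > 0)
  side <- sqrt(vois_per_layer)
  if (side != floor(side)) {
    rlang::abort("vois_per_layer must be a perfect square (in-plane grid)")
  }
  side <- as.integer(side)
  edge <- voi_edge_cm * 10  # mm

  if (is.null(dim)) {
    extent <- c(side * edge, side * edge, layers * edge)
  } else {
    stopifnot(length(dim) == 3, length(spacing) == 3)
    extent <- dim * spacing
  }
  need <- c(side * edge, side * edge, layers * edge)
  over <- need - extent
  if (any(over > 1e-9)) {
    ax <- c("x", "y", "z")[over > 1e-9]
    rlang::abort(paste0("VOI grid exceeds image extent along ",
                        paste(ax, collapse = ", "), " by ",
                        paste(signif(over[over > 1e-9], 4), collapse = ", "),
                        " mm"))
  }
  # centre the grid within the extent
  off <- origin + (extent - need) / 2

  idx <- expand.grid(col = seq_len(side), row = seq_len(side),
                     layer = seq_len(layers))
  g <- tibble::tibble(
    voi_id = seq_len(nrow(idx)),
    layer = idx$layer, row = idx$row, col = idx$col,
    x0 = off[1] + (idx$col - 1) * edge, x1 = off[1] + idx$col * edge,
    y0 = off[2] + (idx$row - 1) * edge, y1 = off[2] + idx$row * edge,
    z0 = off[3] + (idx$layer - 1) * edge, z1 = off[3] + idx$layer * edge
  )
  class(g) <- c("voi_grid", class(g))
  g
}
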