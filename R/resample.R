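#' Resample a CT volume to a target voxel spacing
#'
#' Separable cosine-windowed-sinc interpolation onto a new voxel grid whose
#' spacing equals `target_spacing`. The output grid shares the input origin;
#' its dimensions are `round(dim * spacing / target_spacing)`. Interpolation
#' weights along each axis use the kernel
#' `sinc(d) * cos(pi * d / (2 m))` for `|d| < m` (window radius `m`,
#' default 3 voxels), renormalised to unit sum so constant images are
#' reproduced exactly and intensities stay in HU. Out-of-range samples are
#' clamped to the edge voxel.
#'
#' @param img 3-d numeric array of HU intensities.
#' @param spacing Numeric length-3, input voxel spacing in mm.
#' @param target_spacing Numeric length-3, output voxel spacing in mm.
#' @param radius Window radius in voxels (default 3).
#' @return 3-d array with attributes `spacing` (the target) and `origin`.
#' @export
resample_volume <- function(img, spacing, target_spacing, radius = 3) {
  if (length(base::dim(img)) != 3) rlang::abort("img must be a 3-d array")
  if (length(spacing) != 3 || anyNA(spacing) || any(spacing <= 0)) {
    rlang::abort("spacing must be 3 positive values (mm)")
  }
  stopifnot(length(target_spacing) == 3, all(target_spacing > 0))

  d_in <- base::dim(img)
  d_out <- pmax(1L, as.integer(round(d_in * spacing / target_spacing)))

  out <- img
  for (ax in 1:3) {
    w <- sinc_weights(d_in[ax], d_out[ax], spacing[ax], target_spacing[ax],
                      radius)
    out <- apply_axis(out, ax, w)
  }
  attr(out, "spacing") <- target_spacing
  attr(out, "origin") <- attr(img, "origin") %||% c(0, 0, 0)
  out
}

# (n_out x n_in) row-stochastic windowed-sinc weight matrix for one axis;
# voxel centres at (i - 1) * spacing
sinc_weights <- function(n_in, n_out, sp_in, sp_out, radius) {
  centre <- (seq_len(n_out) - 1) * sp_out / sp_in  # in input-index units
  w <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    u <- centre[j]
    k <- floor(u - radius + 1):ceiling(u + radius - 1e-12)
    d <- u - k
    keep <- abs(d) < radius
    k <- k[keep]; d <- d[keep]
    wk <- ifelse(abs(d) < 1e-12, 1,
                 sin(pi * d) / (pi * d) * cos(pi * d / (2 * radius)))
    k <- pmin(pmax(k, 0L), n_in - 1L)  # clamp to edge
    row <- numeric(n_in)
    for (i in seq_along(k)) row[k[i] + 1L] <- row[k[i] + 1L] + wk[i]
    w[j, ] <- row / sum(wk)
  }
  w
}

# multiply weight matrix along axis `ax` of a 3-d array
apply_axis <- function(a, ax, w) {
  d <- base::dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(a, perm)
  m <- w %*% matrix(a, nrow = d[ax])
  d2 <- c(nrow(w), d[setdiff(1:3, ax)])
  a <- array(m, dim = d2)
  aperm(a, order(perm))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
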