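#' Configuration for the synthetic phantom-study generator
#'
#' Defines the study conditions the generator emulates: a multi-vendor pool
#' of acquisition settings (vendor-specific models and kernels drawn from
#' the default kernel schema, log-spaced numeric parameter grids spanning
#' typical CT protocols) and a feature-distortion model in which each
#' sensitive feature responds multiplicatively to the standardised
#' parameter distortions, with effect sizes ordered kernel > slice
#' thickness > pixel spacing >> noise parameters, and vendor/model having
#' no effect — the effect ordering reported for real phantom data. A small
#' set of designed-insensitive first-order features (mean, median, root
#' mean squared, total energy by default) has all effects zero.
#'
#' @param n_scans Number of scans (default 40, i.e. 780 pairs; use 251 for
#'   a full-scale emulation).
#' @param effects Named non-negative effect sizes per parameter (relative
#'   feature distortion per standard unit of parameter difference).
#' @param noise_sd Additive measurement noise sd on feature values
#'   (default 1; VOI texture signatures have sd 20, so undistorted
#'   features sit at CCC ~ 400/401).
#' @param n_insensitive Number of designed-insensitive features
#'   (default 4).
#' @param voi_dependent If `TRUE`, distortions interact with the VOI
#'   texture signature (a regime that location/scale harmonization cannot
#'   remove); default `FALSE`, the harmonization-favourable regime.
#' @param layers,vois_per_layer Phantom grid (default 10 x 16 = 160 VOIs).
#' @param seed Integer master seed.
#' @return A `generator_config` list, including the parameter pools,
#'   numeric grids and kernel schema used for sampling.
#' @export
generator_config <- function(n_scans = 40,
                             effects = c(vendor = 0, model = 0,
                                         tube_current = 0.005,
                                         exposure = 0.005,
                                         exposure_time = 0.005,
                                         slice_thickness = 0.12,
                                         pixel_spacing = 0.06,
                                         kernel = 0.20),
                             noise_sd = 1, n_insensitive = 4,
                             voi_dependent = FALSE,
                             layers = 10, vois_per_layer = 16,
                             seed = 1L) {
  stopifnot(n_scans >= 2, noise_sd >= 0, n_insensitive >= 0)
  effects <- effects[scan_parameters()]
  if (anyNA(effects) || any(effects < 0)) {
    rlang::abort("effects must cover all eight parameters, non-negative")
  }
  pools <- list(
    vendor = c("GE", "Siemens", "Philips", "Canon"),
    models = list(GE = c("LightSpeed16", "Discovery750"),
                  Siemens = c("Sensation64", "DefinitionAS"),
                  Philips = c("Brilliance64", "iCT256"),
                  Canon = c("Aquilion64", "AquilionONE")),
    kernels = list(GE = c("SOFT", "STANDARD", "CHEST", "BONE", "LUNG"),
                   Siemens = c("B20f", "B31f", "B45f", "B60f", "B70f"),
                   Philips = c("A", "B", "C", "D", "YC"),
                   Canon = c("FC01", "FC08", "FC18", "FC30", "FC50"))
  )
  grids <- list(
    tube_current = c(100, 150, 200, 250, 300, 350, 400),
    exposure = c(50, 100, 150, 200, 250, 300),
    exposure_time = c(500, 750, 1000, 1500),
    slice_thickness = c(1, 1.25, 1.5, 2, 2.5, 3, 3.75, 5),
    pixel_spacing = c(0.49, 0.59, 0.68, 0.78, 0.88, 0.98)
  )
  structure(list(
    n_scans = n_scans, effects = effects, noise_sd = noise_sd,
    n_insensitive = n_insensitive, voi_dependent = voi_dependent,
    layers = layers, vois_per_layer = vois_per_layer,
    pools = pools, grids = grids, schema = default_kernel_schema(),
    base_mu_range = c(50, 150), base_sd = 20, effect_jitter = c(0.5, 1.5),
    sens_sdlog = 1, sens_min = 0.4,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate synthetic scan acquisition metadata
#'
#' Samples `n_scans` acquisition settings from the configured pools:
#' vendor uniformly, model and kernel from the vendor-specific pools,
#' numeric parameters uniformly from their grids. Reproducible for a fixed
#' config seed.
#'
#' @param cfg A [generator_config()].
#' @return A `scan_metadata` tibble of `n_scans` rows.
#' @export
generate_metadata <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  draw <- function(pool) pool[sample.int(length(pool), cfg$n_scans,
                                         replace = TRUE)]
  vendor <- draw(cfg$pools$vendor)
  pick <- function(pool_list, v) {
    vapply(v, function(vi) {
      pool <- pool_list[[vi]]
      pool[sample.int(length(pool), 1)]
    }, character(1))
  }
  meta <- tibble::tibble(
    scan_id = sprintf("scan%03d", seq_len(cfg$n_scans)),
    vendor = vendor,
    model = pick(cfg$pools$models, vendor),
    tube_current = draw(cfg$grids$tube_current),
    exposure = draw(cfg$grids$exposure),
    exposure_time = draw(cfg$grids$exposure_time),
    slice_thickness = draw(cfg$grids$slice_thickness),
    pixel_spacing = draw(cfg$grids$pixel_spacing),
    kernel = pick(cfg$pools$kernels, vendor)
  )
  scan_metadata(meta)
}

# standardised distortion value of each scan for each parameter:
# log-scale z-score against the configured grid (ranks for kernels,
# centred level codes for vendor/model)
distortion_values <- function(meta, cfg) {
  zgrid <- function(v, grid) {
    lg <- log(grid)
    (log(v) - mean(lg)) / stats::sd(lg)
  }
  lev <- function(v, levels) {
    code <- match(v, levels)
    as.numeric(scale(seq_along(levels)))[code]
  }
  ranks <- cfg$schema$rank[match(meta$kernel, cfg$schema$kernel)]
  d <- cbind(
    vendor = lev(meta$vendor, cfg$pools$vendor),
    model = lev(meta$model, sort(unique(unlist(cfg$pools$models)))),
    tube_current = zgrid(meta$tube_current, cfg$grids$tube_current),
    exposure = zgrid(meta$exposure, cfg$grids$exposure),
    exposure_time = zgrid(meta$exposure_time, cfg$grids$exposure_time),
    slice_thickness = zgrid(meta$slice_thickness,
                            cfg$grids$slice_thickness),
    pixel_spacing = zgrid(meta$pixel_spacing, cfg$grids$pixel_spacing),
    kernel = zgrid(ranks, sort(unique(cfg$schema$rank)))
  )
  rownames(d) <- meta$scan_id
  d
}

#' Simulate phantom feature tables with known ground truth
#'
#' Generates one 160-VOI x 91-feature table per scan under the distortion
#' model
#' \deqn{y_{vf} = b_{vf}\,\bigl(1 + \sum_p \beta_{fp}\, d_p\bigr) +
#'   \varepsilon,\qquad \varepsilon \sim N(0, \mathrm{noise\_sd}^2),}
#' where \eqn{b_{vf}} is a fixed per-VOI texture signature shared by all
#' scans, \eqn{d_p} the scan's standardised parameter distortion and
#' \eqn{\beta_{fp}} the feature's effect size (the configured per-parameter
#' effect jittered per feature; zero for the designed-insensitive
#' features). With `voi_dependent = TRUE` the distortion is additionally
#' modulated per VOI, creating batch effects that location/scale
#' harmonization cannot remove.
#'
#' @param meta Scan metadata from [generate_metadata()] (or compatible).
#' @param cfg The [generator_config()] used to generate `meta`.
#' @return List with `features` (stacked feature table, arm `"original"`)
#'   and `truth` (effect matrix `beta`, per-scan distortions `d`,
#'   `insensitive` feature names, the VOI modulation).
#' @export
simulate_features <- function(meta, cfg = generator_config()) {
  if (cfg$noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  registry <- feature_registry()
  n_voi <- cfg$layers * cfg$vois_per_layer
  n_f <- nrow(registry)

  insensitive_pool <- paste0("original_firstorder_",
                             c("Mean", "Median", "RootMeanSquared",
                               "TotalEnergy", "Energy", "10Percentile",
                               "90Percentile", "Maximum"))
  insensitive <- utils::head(insensitive_pool, cfg$n_insensitive)

  set.seed(cfg$seed + 1000003L)
  mu <- stats::runif(n_f, cfg$base_mu_range[1], cfg$base_mu_range[2])
  base <- matrix(stats::rnorm(n_voi * n_f, 0, cfg$base_sd), n_voi, n_f)
  base <- sweep(base, 2, mu, `+`)
  colnames(base) <- registry$feature

  # Per-feature overall sensitivity is heavy-tailed (real features span
  # orders of magnitude in parameter sensitivity) and bounded away from
  # zero so every sensitive feature fails somewhere under extreme
  # differences. Each sensitive feature responds to one dominant
  # parameter (texture features track the kernel, volume-averaging
  # features the slice thickness, ...), drawn with probability
  # proportional to the configured effect sizes.
  sens <- pmax(stats::rlnorm(n_f, meanlog = 0, sdlog = cfg$sens_sdlog),
               cfg$sens_min)
  resolution <- c("kernel", "slice_thickness", "pixel_spacing")
  noisep <- c("tube_current", "exposure", "exposure_time")
  pr <- cfg$effects[resolution]
  beta <- matrix(0, n_f, 8,
                 dimnames = list(registry$feature, scan_parameters()))
  if (sum(pr) > 0) {
    dominant <- sample(resolution, n_f, replace = TRUE, prob = pr / sum(pr))
    jitter <- stats::runif(n_f, cfg$effect_jitter[1], cfg$effect_jitter[2])
    beta[cbind(seq_len(n_f), match(dominant, scan_parameters()))] <-
      cfg$effects[dominant] * jitter * sens
  }
  # weak dose/noise-parameter response shared by all sensitive features
  for (p in noisep) {
    beta[, p] <- cfg$effects[p] * sens *
      stats::runif(n_f, cfg$effect_jitter[1], cfg$effect_jitter[2])
  }
  beta[registry$feature %in% insensitive, ] <- 0

  voi_mod <- if (cfg$voi_dependent) {
    stats::runif(n_voi, -0.5, 0.5)
  } else {
    rep(0, n_voi)
  }

  d <- distortion_values(meta, cfg)
  tables <- purrr::map(seq_len(nrow(meta)), function(s) {
    shift <- as.numeric(beta %*% d[s, ])          # per-feature distortion
    fac <- 1 + outer(1 + voi_mod, shift)          # VOI x feature factor
    vals <- base * fac +
      matrix(stats::rnorm(n_voi * n_f, 0, cfg$noise_sd), n_voi, n_f)
    dplyr::bind_cols(
      tibble::tibble(scan_id = meta$scan_id[s], arm = "original",
                     voi_id = seq_len(n_voi)),
      tibble::as_tibble(as.data.frame(vals)))
  })
  list(features = dplyr::bind_rows(tables),
       truth = list(beta = beta, d = d, insensitive = insensitive,
                    voi_mod = voi_mod, base_mu = mu))
}

#' Simulate a complete synthetic phantom study
#'
#' @param cfg A [generator_config()].
#' @return List: `metadata` (scan metadata), `features` (stacked feature
#'   table), `truth` (generator ground truth).
#' @export
#' @examples
#' study <- simulate_study(generator_config(n_scans = 4, seed = 7))
#' dim(study$features)
simulate_study <- function(cfg = generator_config()) {
  meta <- generate_metadata(cfg)
  sim <- simulate_features(meta, cfg)
  list(metadata = meta, features = sim$features, truth = sim$truth)
}
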