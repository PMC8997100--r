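#' Fit an empirical-Bayes batch-effect (ComBat) model
#'
#' Location/scale batch-effect model with empirical-Bayes shrinkage, the
#' harmonization method originally developed for gene-expression arrays and
#' here applied to radiomic feature tables. Each feature g is standardised
#' with its grand mean \eqn{\hat\alpha_g} and pooled variance
#' \eqn{\hat\sigma^2_g}; per batch i the additive effect
#' \eqn{\gamma_{ig}} and multiplicative effect \eqn{\delta^2_{ig}} of the
#' standardised data are estimated and shrunk toward parametric priors
#' (normal for \eqn{\gamma}, inverse-gamma for \eqn{\delta^2}) by iterating
#' the conditional posterior means to convergence. Phantom use has no
#' biological covariates: rows of the same VOI index are replicates of the
#' same ground truth, so only batch indicators enter the model. In the
#' pairwise scenario analysis each scan of a pair is one batch of 160 VOIs.
#'
#' @param x Samples x features numeric matrix, or a stacked feature table
#'   tibble (then `batch` defaults to its `scan_id`).
#' @param batch Batch label per row.
#' @param parametric Use parametric priors (default); `FALSE` selects the
#'   non-parametric weighted posterior.
#' @param tol,max_iter Convergence control for the parametric EB iteration
#'   (relative change, default 1e-4 / 100 iterations).
#' @return A `combat_model`: per-feature grand parameters, per-batch
#'   EB-shrunken effects, prior hyperparameters, and the names of
#'   zero-variance features passed through unadjusted.
#' @export
fit_combat <- function(x, batch = NULL, parametric = TRUE,
                       tol = 1e-4, max_iter = 100) {
  prep <- combat_prep(x, batch)
  x <- prep$x; batch <- prep$batch
  batches <- unique(batch)
  if (length(batches) < 2) {
    rlang::abort("need at least 2 batches to harmonize")
  }
  n_i <- table(factor(batch, levels = batches))
  if (any(n_i < 2)) rlang::abort("every batch needs at least 2 samples")
  n <- nrow(x); g <- ncol(x)

  bm <- rowsum(x, batch)[batches, , drop = FALSE] / as.numeric(n_i)
  alpha <- colSums(bm * as.numeric(n_i)) / n
  resid <- x - bm[match(batch, batches), , drop = FALSE]
  sigma2 <- colMeans(resid^2)
  zero_var <- sigma2 <= .Machine$double.eps * pmax(1, abs(alpha))^2
  sig <- sqrt(ifelse(zero_var, 1, sigma2))

  z <- sweep(sweep(x, 2, alpha), 2, sig, `/`)
  gamma_hat <- rowsum(z, batch)[batches, , drop = FALSE] / as.numeric(n_i)
  delta2_hat <- (rowsum(z^2, batch)[batches, , drop = FALSE] -
                   as.numeric(n_i) * gamma_hat^2) /
    pmax(as.numeric(n_i) - 1, 1)
  delta2_hat <- pmax(delta2_hat, .Machine$double.eps)

  gamma_bar <- rowMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta2_hat)
  s2 <- apply(delta2_hat, 1, stats::var)
  a_prior <- (2 * s2 + m^2) / pmax(s2, .Machine$double.eps)
  b_prior <- (m * s2 + m^3) / pmax(s2, .Machine$double.eps)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_along(batches)) {
    zi <- z[batch == batches[i], , drop = FALSE]
    ni <- nrow(zi)
    if (parametric) {
      gs <- gamma_hat[i, ]; ds <- delta2_hat[i, ]
      for (it in seq_len(max_iter)) {
        gs_new <- (ni * tau2_bar[i] * gamma_hat[i, ] + ds * gamma_bar[i]) /
          (ni * tau2_bar[i] + ds)
        ss <- colSums(sweep(zi, 2, gs_new)^2)
        ds_new <- (b_prior[i] + 0.5 * ss) / (ni / 2 + a_prior[i] - 1)
        change <- max(abs(gs_new - gs) / pmax(abs(gs), 1e-12),
                      abs(ds_new - ds) / pmax(abs(ds), 1e-12))
        gs <- gs_new; ds <- ds_new
        if (change < tol) break
      }
      gamma_star[i, ] <- gs
      delta2_star[i, ] <- ds
    } else {
      ep <- combat_eprior(zi, gamma_hat[i, ], delta2_hat[i, ])
      gamma_star[i, ] <- ep$gamma
      delta2_star[i, ] <- ep$delta2
    }
  }
  gamma_star[, zero_var] <- 0
  delta2_star[, zero_var] <- 1

  structure(list(
    batches = batches, n_per_batch = as.integer(n_i),
    features = colnames(x), alpha = alpha, sigma2 = sigma2,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2_bar = tau2_bar,
    a_prior = a_prior, b_prior = b_prior,
    parametric = parametric, zero_var = colnames(x)[zero_var]
  ), class = "combat_model")
}

# non-parametric EB: posterior weights from the other features' estimates
combat_eprior <- function(zi, g_hat, d_hat) {
  g <- length(g_hat)
  gamma <- g_hat; delta2 <- d_hat
  for (j in seq_len(g)) {
    oth <- setdiff(seq_len(g), j)
    x <- zi[, j]
    ll <- vapply(oth, function(h) {
      sum(stats::dnorm(x, g_hat[h], sqrt(d_hat[h]), log = TRUE))
    }, numeric(1))
    w <- exp(ll - max(ll))
    gamma[j] <- sum(g_hat[oth] * w) / sum(w)
    delta2[j] <- sum(d_hat[oth] * w) / sum(w)
  }
  list(gamma = gamma, delta2 = delta2)
}

combat_prep <- function(x, batch) {
  if (is.data.frame(x)) {
    if (is.null(batch)) batch <- x$scan_id
    x <- as.matrix(x[, feature_cols(x), drop = FALSE])
  }
  if (is.null(batch)) rlang::abort("batch labels are required")
  if (length(batch) != nrow(x)) rlang::abort("batch length != rows of x")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, batch = as.character(batch))
}

#' Apply a fitted ComBat model
#'
#' Adjusts data from batches seen at fit time:
#' \eqn{y^* = \hat\sigma_g (z - \gamma^*_{ig}) / \delta^*_{ig} +
#' \hat\alpha_g} with \eqn{z = (y - \hat\alpha_g)/\hat\sigma_g}.
#' Zero-variance features recorded by [fit_combat()] pass through
#' unchanged. Shape and feature order are preserved.
#'
#' @param model A `combat_model`.
#' @param x Samples x features matrix or stacked feature table (same
#'   features as at fit time).
#' @param batch Batch label per row; every label must have been seen at fit
#'   time.
#' @return Adjusted data in the same form as `x` (matrix in, matrix out;
#'   tibble in, tibble out).
#' @export
apply_combat <- function(model, x, batch = NULL) {
  tabular <- is.data.frame(x)
  orig <- x
  prep <- combat_prep(x, batch)
  xm <- prep$x; batch <- prep$batch
  if (!identical(colnames(xm), model$features)) {
    rlang::abort("features differ from those seen at fit time")
  }
  unknown <- setdiff(unique(batch), model$batches)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown batch label(s): ",
                        paste(unknown, collapse = ", ")))
  }
  i <- match(batch, model$batches)
  sig <- sqrt(ifelse(model$sigma2 <= 0, 1, model$sigma2))
  z <- sweep(sweep(xm, 2, model$alpha), 2, sig, `/`)
  adj <- (z - model$gamma_star[i, , drop = FALSE]) /
    sqrt(model$delta2_star[i, , drop = FALSE])
  out <- sweep(sweep(adj, 2, sig, `*`), 2, model$alpha, `+`)
  keep <- model$features %in% model$zero_var
  out[, keep] <- xm[, keep]
  if (tabular) {
    orig[, model$features] <- tibble::as_tibble(as.data.frame(out))
    orig
  } else {
    out
  }
}

#' Harmonize the two feature tables of a scan pair
#'
#' Convenience wrapper: stacks the two tables, fits two-batch ComBat (one
#' batch per scan) and returns the adjusted tables.
#'
#' @param ta,tb Single-scan feature tables with aligned VOIs.
#' @inheritParams fit_combat
#' @return List with elements `a`, `b` (adjusted tables) and `model`.
#' @export
harmonize_pair <- function(ta, tb, parametric = TRUE) {
  x <- dplyr::bind_rows(ta, tb)
  fit <- fit_combat(x, batch = x$scan_id, parametric = parametric)
  adj <- apply_combat(fit, x, batch = x$scan_id)
  list(a = adj[seq_len(nrow(ta)), ],
       b = adj[nrow(ta) + seq_len(nrow(tb)), ],
       model = fit)
}

#' Serialize / restore a ComBat model
#'
#' @param model A `combat_model`.
#' @param path JSON file path.
#' @return `write_combat_model()`: `path` invisibly; `read_combat_model()`:
#'   the restored `combat_model`.
#' @export
write_combat_model <- function(model, path) {
  obj <- purrr::map(unclass(model), function(v) {
    if (is.matrix(v)) list(dim = dim(v), data = as.numeric(v)) else v
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- c("gamma_hat", "delta2_hat", "gamma_star", "delta2_star")
  for (m in mats) {
    obj[[m]] <- matrix(obj[[m]]$data, nrow = obj[[m]]$dim[1])
  }
  for (v in c("alpha", "sigma2")) {
    obj[[v]] <- stats::setNames(as.numeric(obj[[v]]), obj$features)
  }
  obj$zero_var <- as.character(obj$zero_var %||% character())
  structure(obj, class = "combat_model")
}
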