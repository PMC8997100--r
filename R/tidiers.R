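#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the importance table of a reproducibility random forest
#'
#' @param x A `repro_rf` fit.
#' @param ... Unused.
#' @return Tibble: `parameter`, `importance`, sorted descending.
#' @method tidy repro_rf
#' @export
tidy.repro_rf <- function(x, ...) x$importance

#' One-row fit summary of a reproducibility random forest
#'
#' @param x A `repro_rf` fit.
#' @param ... Unused.
#' @return Tibble: `n_pairs`, `n_trees`, `mtry`, `var_explained`,
#'   `importance_method`, `seed`.
#' @method glance repro_rf
#' @export
glance.repro_rf <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_trees = x$n_trees, mtry = x$mtry,
                 var_explained = x$var_explained,
                 importance_method = x$importance_method, seed = x$seed)
}

#' Tidy MaasPenn score weights
#'
#' @param x A `maaspenn_weights` vector.
#' @param ... Unused.
#' @return Tibble: `parameter`, `weight`, `provenance`.
#' @method tidy maaspenn_weights
#' @export
tidy.maaspenn_weights <- function(x, ...) {
  tibble::tibble(parameter = names(x), weight = as.numeric(x),
                 provenance = attr(x, "provenance"))
}

#' Tidy a fitted ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Long tibble of per-batch, per-feature effect estimates:
#'   `batch`, `feature`, `gamma_hat`, `delta2_hat`, `gamma_star`,
#'   `delta2_star`.
#' @method tidy combat_model
#' @export
tidy.combat_model <- function(x, ...) {
  grid <- expand.grid(batch = x$batches, feature = x$features,
                      stringsAsFactors = FALSE)
  i <- match(grid$batch, x$batches)
  j <- match(grid$feature, x$features)
  tibble::tibble(
    batch = grid$batch, feature = grid$feature,
    gamma_hat = x$gamma_hat[cbind(i, j)],
    delta2_hat = x$delta2_hat[cbind(i, j)],
    gamma_star = x$gamma_star[cbind(i, j)],
    delta2_star = x$delta2_star[cbind(i, j)]
  )
}

#' One-row summary of a fitted ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return Tibble: `n_batches`, `n_features`, `n_zero_var`, `parametric`.
#' @method glance combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(n_batches = length(x$batches),
                 n_features = length(x$features),
                 n_zero_var = length(x$zero_var),
                 parametric = x$parametric)
}
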