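#' Fit the random-forest model of reproducibility on encoded parameters
#'
#' Regression random forest of the percentage of reproducible features per
#' scenario on the eight encoded acquisition parameters (500 trees, three
#' variables per split by default). Reports percent variance explained and
#' per-parameter importance; permutation importance (mean decrease in MSE,
#' unscaled) is the default measure, impurity (node-purity) importance is
#' available via `importance_method = "impurity"`.
#'
#' @param data Tibble holding the encoded parameter columns
#'   ([scan_parameters()]) and the outcome column.
#' @param outcome Name of the outcome column (default
#'   `"pct_reproducible"`), values in \[0, 100\].
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried per split (default 3).
#' @param importance_method `"permutation"` (default) or `"impurity"`.
#' @param seed Integer seed making the fit deterministic.
#' @return Object of class `repro_rf`: the randomForest fit plus the
#'   importance table, percent variance explained and the configuration.
#' @export
fit_reproducibility_rf <- function(data, outcome = "pct_reproducible",
                                   n_trees = 500, mtry = 3,
                                   importance_method = c("permutation",
                                                         "impurity"),
                                   seed = 1L) {
  importance_method <- match.arg(importance_method)
  params <- scan_parameters()
  missing_cols <- setdiff(c(params, outcome), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("data is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]]
  if (anyNA(y) || any(y < 0 | y > 100)) {
    rlang::abort("outcome must be a percentage in [0, 100] without NAs")
  }
  if (stats::var(y) == 0) rlang::abort("outcome is constant; nothing to fit")
  if (nrow(data) < 50) rlang::abort("need at least 50 pairs to fit")
  stopifnot(n_trees >= 1, mtry >= 1, mtry <= length(params))

  x <- as.data.frame(data[, params])
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    importance = (importance_method == "permutation")
  )
  imp_raw <- randomForest::importance(
    fit, type = if (importance_method == "permutation") 1 else 2,
    scale = FALSE)
  imp <- tibble::tibble(parameter = rownames(imp_raw),
                        importance = as.numeric(imp_raw[, 1]))
  imp <- dplyr::arrange(imp, dplyr::desc(.data$importance))

  structure(list(
    fit = fit,
    importance = imp,
    importance_method = importance_method,
    var_explained = 100 * (1 - fit$mse[n_trees] / mean((y - mean(y))^2)),
    n_pairs = nrow(data), outcome = outcome,
    n_trees = n_trees, mtry = mtry, seed = seed
  ), class = "repro_rf")
}

#' @export
print.repro_rf <- function(x, ...) {
  cat("Reproducibility random forest (", x$n_trees, " trees, mtry ",
      x$mtry, ")\n", sep = "")
  cat("  pairs: ", x$n_pairs, "; variance explained: ",
      sprintf("%.1f%%", x$var_explained), "\n", sep = "")
  cat("  importance (", x$importance_method, "):\n", sep = "")
  for (i in seq_len(nrow(x$importance))) {
    cat(sprintf("    %-16s %8.3f\n", x$importance$parameter[i],
                x$importance$importance[i]))
  }
  invisible(x)
}

#' Derive score weights from parameter importances
#'
#' Retains the `k` most important parameters and normalises their
#' importances to sum to 1: each retained parameter's weight is its
#' importance divided by the total importance of the retained set. Small
#' negative permutation importances are clamped to zero before
#' normalisation.
#'
#' @param importances A `repro_rf` object, or a tibble/named vector of
#'   per-parameter importances.
#' @param k Number of parameters to retain (default 3).
#' @return Object of class `maaspenn_weights`: a named weight vector
#'   summing to 1, with a `provenance` attribute `"fitted"`.
#' @export
derive_weights <- function(importances, k = 3) {
  if (inherits(importances, "repro_rf")) importances <- importances$importance
  if (is.data.frame(importances)) {
    importances <- stats::setNames(importances$importance,
                                   importances$parameter)
  }
  if (k > length(importances)) {
    rlang::abort("k exceeds the number of parameters")
  }
  if (any(importances < 0)) {
    importances <- pmax(importances, 0)
  }
  top <- sort(importances, decreasing = TRUE)[seq_len(k)]
  if (sum(top) == 0) rlang::abort("retained importances are all zero")
  w <- top / sum(top)
  new_weights(w, provenance = "fitted")
}

new_weights <- function(w, provenance) {
  stopifnot(abs(sum(w) - 1) < 1e-9, all(w >= 0),
            all(names(w) %in% scan_parameters()))
  structure(w, provenance = provenance, class = "maaspenn_weights")
}

#' The published MaasPenn score weights
#'
#' The score retains the three resolution parameters, weighted by their
#' normalised random-forest importance on the 31,375-pair phantom analysis:
#' convolution kernel 48%, slice thickness 33%, pixel spacing 19%.
#'
#' @return A `maaspenn_weights` vector with `provenance = "published"`.
#' @export
#' @examples
#' published_weights()
published_weights <- function() {
  new_weights(c(kernel = 0.48, slice_thickness = 0.33,
                pixel_spacing = 0.19),
              provenance = "published")
}

#' @export
print.maaspenn_weights <- function(x, ...) {
  cat("MaasPenn score weights (", attr(x, "provenance"), ")\n", sep = "")
  for (p in names(x)) cat(sprintf("  %-16s %.3f\n", p, x[[p]]))
  invisible(x)
}
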