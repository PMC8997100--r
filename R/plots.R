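#' Boxplot of reproducible-feature percentages across scenarios
#'
#' One box per processing arm and harmonization status, mirroring the
#' standard view of how reproducibility is distributed over scan pairs.
#'
#' @param scenarios Scenario tibble from [compute_scenarios()] (several
#'   arms may be bound together).
#' @return A ggplot object.
#' @export
plot_scenario_distribution <- function(scenarios) {
  scenarios$group <- paste0(scenarios$arm,
                            ifelse(scenarios$harmonized, " + ComBat", ""))
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(x = .data$group,
                               y = .data$pct_reproducible)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "Reproducible features (%)",
                  title = "Reproducibility across scan-pair scenarios") +
    ggplot2::theme_minimal()
}

#' Variable-importance plot of the reproducibility random forest
#'
#' @param x A `repro_rf` fit.
#' @return A ggplot object.
#' @export
plot_importance <- function(x) {
  imp <- x$importance
  imp$parameter <- factor(imp$parameter,
                          levels = rev(imp$parameter))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("importance (", x$importance_method, ")"),
                  y = NULL,
                  title = "Acquisition-parameter importance") +
    ggplot2::theme_minimal()
}

#' Score versus percent-reproducible scatter plot
#'
#' @param scores,pct_reproducible Per-pair score and outcome vectors.
#' @return A ggplot object annotated with Spearman's rho.
#' @export
plot_score_vs_outcome <- function(scores, pct_reproducible) {
  rho <- score_outcome_correlation(scores, pct_reproducible)
  ggplot2::ggplot(tibble::tibble(score = scores, pct = pct_reproducible),
                  ggplot2::aes(x = .data$score, y = .data$pct)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::labs(x = "MaasPenn score", y = "Reproducible features (%)",
                  subtitle = sprintf("Spearman rho = %.2f", rho)) +
    ggplot2::theme_minimal()
}

#' AUC distributions across robustness runs
#'
#' Boxplots of training and validation AUC per reproducibility threshold
#' over the repeated random splits.
#'
#' @param runs Output of [robustness_runs()].
#' @return A ggplot object.
#' @export
plot_robustness <- function(runs) {
  runs <- runs[!is.na(runs$auc), ]
  ggplot2::ggplot(runs,
                  ggplot2::aes(x = factor(.data$pct_threshold),
                               y = .data$auc, fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = "Reproducibility threshold (%)", y = "AUC",
                  fill = NULL,
                  title = "Score robustness across random splits") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot repro_rf
#' @export
autoplot.repro_rf <- function(object, ...) plot_importance(object)
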