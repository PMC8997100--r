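#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two measurements of the same quantity,
#' penalising both location and scale shifts in addition to imperfect
#' correlation:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar x - \bar y)^2}.}
#' Moments use the population (1/n) estimator by default, per Lin's
#' original definition; `moments = "sample"` switches to 1/(n-1) moments
#' (the convention of some epidemiology implementations — at n = 160 the
#' difference is negligible but the choice is explicit).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param moments `"population"` (default) or `"sample"`.
#' @return A number in \[-1, 1\]; `NA` (flagged by a warning-free
#'   degenerate case) when both vectors are constant, in which case
#'   concordance is undefined.
#' @export
#' @examples
#' lin_ccc(c(0, 1, 2), c(1, 2, 3))  # 4/7: perfect correlation, shifted
lin_ccc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(x) != length(y)) rlang::abort("x and y lengths differ")
  n <- length(x)
  if (n < 2) rlang::abort("need at least 2 paired values")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  if (moments == "sample") {
    f <- n / (n - 1)
    vx <- vx * f; vy <- vy * f; cxy <- cxy * f
  }
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * cxy / den
}

#' Per-feature concordance between two feature tables
#'
#' Computes [lin_ccc()] for every feature column across the VOI-aligned rows
#' of two single-scan feature tables and flags each feature reproducible iff
#' its CCC strictly exceeds the threshold. Features that are constant in
#' both tables have undefined concordance: their CCC is `NA`, flagged
#' `degenerate`, and they count as non-reproducible.
#'
#' @param ta,tb Feature tables (same registry, same arm, same VOIs).
#' @param threshold Reproducibility threshold on CCC (default 0.9, strict
#'   `>`).
#' @param moments Passed to [lin_ccc()].
#' @return Tibble: `feature`, `ccc`, `n`, `reproducible`, `degenerate`.
#' @export
pair_ccc <- function(ta, tb, threshold = 0.9,
                     moments = c("population", "sample")) {
  moments <- match.arg(moments)
  fc <- feature_cols(ta)
  if (!identical(fc, feature_cols(tb))) {
    rlang::abort("feature tables have different feature columns")
  }
  a <- feature_matrix(ta); b <- feature_matrix(tb)
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    rlang::abort("VOI rows are not aligned between the two tables")
  }
  ccc <- ccc_columns(a, b, moments)
  tibble::tibble(
    feature = fc, ccc = ccc, n = nrow(a),
    reproducible = !is.na(ccc) & ccc > threshold,
    degenerate = is.na(ccc)
  )
}

# vectorised per-column CCC between aligned matrices
ccc_columns <- function(a, b, moments = "population") {
  n <- nrow(a)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colMeans(a^2) - ma^2
  vb <- colMeans(b^2) - mb^2
  cab <- colMeans(a * b) - ma * mb
  if (moments == "sample") {
    f <- n / (n - 1)
    va <- va * f; vb <- vb * f; cab <- cab * f
  }
  den <- va + vb + (ma - mb)^2
  out <- 2 * cab / den
  out[den <= 0] <- NA_real_
  unname(out)
}

#' Reproducibility of one scan-pair scenario
#'
#' Summarises [pair_ccc()] for one scenario (an unordered pair of scans
#' processed under the same arm): the number and percentage of registry
#' features whose CCC exceeds the threshold.
#'
#' @inheritParams pair_ccc
#' @param harmonized Logical flag recorded in the output (set by the
#'   harmonization arm of the analysis).
#' @return One-row tibble: `pair_id`, `scan_a`, `scan_b`, `arm`,
#'   `harmonized`, `n_features`, `n_reproducible`, `pct_reproducible`, and
#'   a list-column `ccc` holding the per-feature [pair_ccc()] tibble.
#' @export
scenario_reproducibility <- function(ta, tb, threshold = 0.9,
                                     harmonized = FALSE,
                                     moments = c("population", "sample")) {
  moments <- match.arg(moments)
  arm_a <- unique(ta$arm); arm_b <- unique(tb$arm)
  if (length(arm_a) != 1 || !identical(arm_a, arm_b)) {
    rlang::abort("both tables must come from the same single processing arm")
  }
  cc <- pair_ccc(ta, tb, threshold = threshold, moments = moments)
  ids <- sort(c(unique(ta$scan_id), unique(tb$scan_id)))
  tibble::tibble(
    pair_id = paste(ids, collapse = ":"), scan_a = ids[1], scan_b = ids[2],
    arm = arm_a, harmonized = harmonized,
    n_features = nrow(cc), n_reproducible = sum(cc$reproducible),
    pct_reproducible = 100 * mean(cc$reproducible),
    ccc = list(cc)
  )
}

#' Reproducibility across all scenarios of a dataset
#'
#' Runs the per-pair concordance analysis over every unordered pair of
#' scans in a stacked feature table, optionally after per-pair ComBat
#' harmonization (each scan of the pair is one batch).
#'
#' @param features Stacked feature table for several scans (one arm).
#' @param pairs Optional pair tibble from [enumerate_pairs()].
#' @param threshold CCC reproducibility threshold (default 0.9, strict).
#' @param harmonize If `TRUE`, fit and apply two-batch ComBat within each
#'   pair before computing concordance.
#' @param moments Passed to [lin_ccc()].
#' @param detail If `TRUE`, keep the per-feature reproducibility flags as a
#'   list-column `flags` (needed by [intersect_reproducible()]).
#' @return Scenario tibble, one row per pair: `pair_id`, `scan_a`,
#'   `scan_b`, `arm`, `harmonized`, `n_features`, `n_reproducible`,
#'   `pct_reproducible` (and `flags` when `detail = TRUE`).
#' @export
compute_scenarios <- function(features, pairs = NULL, threshold = 0.9,
                              harmonize = FALSE,
                              moments = c("population", "sample"),
                              detail = FALSE) {
  moments <- match.arg(moments)
  arm <- unique(features$arm)
  if (length(arm) != 1) {
    rlang::abort("features must contain a single processing arm; filter first")
  }
  ids <- unique(features$scan_id)
  if (is.null(pairs)) pairs <- enumerate_pairs(ids)
  mats <- purrr::map(split(features, features$scan_id), feature_matrix)
  fc <- feature_cols(features)

  one <- function(a_id, b_id) {
    a <- mats[[a_id]]; b <- mats[[b_id]]
    if (harmonize) {
      x <- rbind(a, b)
      batch <- rep(c(a_id, b_id), c(nrow(a), nrow(b)))
      fit <- fit_combat(x, batch)
      x <- apply_combat(fit, x, batch)
      a <- x[seq_len(nrow(a)), , drop = FALSE]
      b <- x[nrow(a) + seq_len(nrow(b)), , drop = FALSE]
    }
    cc <- ccc_columns(a, b, moments)
    !is.na(cc) & cc > threshold
  }
  flags <- purrr::map2(pairs$scan_a, pairs$scan_b, one)
  out <- tibble::tibble(
    pair_id = pairs$pair_id, scan_a = pairs$scan_a, scan_b = pairs$scan_b,
    arm = arm, harmonized = harmonize,
    n_features = length(fc),
    n_reproducible = purrr::map_int(flags, sum)
  )
  out$pct_reproducible <- 100 * out$n_reproducible / out$n_features
  if (detail) out$flags <- purrr::map(flags, ~stats::setNames(.x, fc))
  out
}

#' Features reproducible in every scenario
#'
#' Intersects the per-feature reproducibility flags across all scenarios:
#' a feature is returned iff it was reproducible in every pair, i.e. it is
#' insensitive to all parameter variations present in the dataset (or, for
#' harmonized scenarios, harmonizable under all of them).
#'
#' @param scenarios Scenario tibble from [compute_scenarios()] with
#'   `detail = TRUE` (or rows built by [scenario_reproducibility()]).
#' @return Character vector of feature names.
#' @export
intersect_reproducible <- function(scenarios) {
  if (nrow(scenarios) == 0) rlang::abort("no scenarios supplied")
  flags <- if ("flags" %in% names(scenarios)) {
    scenarios$flags
  } else if ("ccc" %in% names(scenarios)) {
    purrr::map(scenarios$ccc,
               ~stats::setNames(.x$reproducible, .x$feature))
  } else {
    rlang::abort("scenarios carry no per-feature flags; rerun with detail = TRUE")
  }
  all_flags <- Reduce(`&`, flags)
  names(all_flags)[all_flags]
}

#' Summarise scenario reproducibility
#'
#' Mean and standard deviation of the number and percentage of reproducible
#' features per processing arm and harmonization status — the boxplot-ready
#' view of how reproducibility is distributed across scenarios.
#'
#' @param scenarios Scenario tibble (rows from [compute_scenarios()],
#'   possibly several arms bound together).
#' @return Tibble grouped by `arm` and `harmonized` with `n_pairs`,
#'   `mean_n`, `sd_n`, `mean_pct`, `sd_pct`.
#' @export
summarize_scenarios <- function(scenarios) {
  if (nrow(scenarios) == 0) rlang::abort("no scenarios supplied")
  dplyr::summarise(
    dplyr::group_by(scenarios, .data$arm, .data$harmonized),
    n_pairs = dplyr::n(),
    mean_n = mean(.data$n_reproducible),
    sd_n = stats::sd(.data$n_reproducible),
    mean_pct = mean(.data$pct_reproducible),
    sd_pct = stats::sd(.data$pct_reproducible),
    .groups = "drop"
  )
}
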