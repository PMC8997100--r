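#' Screen scans for inclusion by pairwise MaasPenn score
#'
#' Prospective quality-check workflow: scores every unordered pair of scans
#' with the published weights and reports which pairs fall at or below the
#' decision cut-off (default 0.94, the cut-off at which 70% or more of
#' features are expected reproducible; a pair passes only with score
#' strictly above it), plus a per-scan summary of how often each scan is
#' involved in a failing pair. Deterministic: a pure function of metadata,
#' schema and cut-off.
#'
#' @param meta A `scan_metadata` tibble (>= 2 scans).
#' @param schema A [kernel_schema()].
#' @param cutoff Decision cut-off on the score (default 0.94).
#' @param weights Score weights (default [published_weights()]).
#' @return List of class `maaspenn_screen`: `pairs` (scored pair tibble
#'   with `pass`), `scans` (per-scan failing-pair counts, worst first),
#'   `cutoff`, `n_fail`.
#' @export
screen_scans <- function(meta, schema = default_kernel_schema(),
                         cutoff = 0.94, weights = published_weights()) {
  scored <- maaspenn_score(encode_pairs(meta, schema = schema),
                           weights = weights)
  scored$pass <- scored$score > cutoff
  fails <- scored[!scored$pass, ]
  per_scan <- tibble::tibble(scan_id = c(scored$scan_a, scored$scan_b),
                             pass = rep(scored$pass, 2))
  per_scan <- dplyr::summarise(dplyr::group_by(per_scan, .data$scan_id),
                               n_pairs = dplyr::n(),
                               n_failing = sum(!.data$pass),
                               min_score = NA_real_, .groups = "drop")
  mins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(scan_id = c(scored$scan_a,
                                               scored$scan_b),
                                   score = rep(scored$score, 2)),
                    .data$scan_id),
    min_score = min(.data$score), .groups = "drop")
  per_scan$min_score <- mins$min_score[match(per_scan$scan_id,
                                             mins$scan_id)]
  per_scan <- dplyr::arrange(per_scan, dplyr::desc(.data$n_failing),
                             .data$min_score)
  structure(list(pairs = scored, scans = per_scan, cutoff = cutoff,
                 n_fail = nrow(fails)), class = "maaspenn_screen")
}

#' @export
print.maaspenn_screen <- function(x, ...) {
  cat("MaasPenn screening at cut-off ", x$cutoff, ": ",
      sum(x$pairs$pass), "/", nrow(x$pairs),
      " pairs pass (", x$n_fail, " fail)\n", sep = "")
  if (x$n_fail > 0) {
    worst <- utils::head(x$scans[x$scans$n_failing > 0, ], 5)
    cat("  scans in most failing pairs:\n")
    for (i in seq_len(nrow(worst))) {
      cat(sprintf("    %-12s %d/%d failing (min score %.3f)\n",
                  worst$scan_id[i], worst$n_failing[i], worst$n_pairs[i],
                  worst$min_score[i]))
    }
  }
  invisible(x)
}

#' Audit a signature-development dataset
#'
#' Retrospective workflow: computes the fraction of scan pairs whose
#' MaasPenn score strictly exceeds the cut-off. When a strict majority of
#' pairs lies above it, features extracted across the dataset are likely
#' concordant and a signature developed on it has a higher chance of
#' generalising.
#'
#' @inheritParams screen_scans
#' @return One-row tibble: `n_pairs`, `n_above`, `fraction_above`,
#'   `cutoff`, `majority_above` (strict > 1/2), `verdict`.
#' @export
audit_signature_dataset <- function(meta, schema = default_kernel_schema(),
                                    cutoff = 0.94,
                                    weights = published_weights()) {
  scored <- maaspenn_score(encode_pairs(meta, schema = schema),
                           weights = weights)
  frac <- mean(scored$score > cutoff)
  maj <- frac > 0.5
  tibble::tibble(
    n_pairs = nrow(scored), n_above = sum(scored$score > cutoff),
    fraction_above = frac, cutoff = cutoff, majority_above = maj,
    verdict = ifelse(maj, "majority above cut-off: generalization likely",
                     "majority not above cut-off: reproducibility at risk")
  )
}
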