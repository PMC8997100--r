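#' ROC analysis of the score against a reproducibility threshold
#'
#' Given per-pair scores and binary labels (1 iff the percentage of
#' reproducible features strictly exceeds a chosen threshold), computes the
#' AUC via the rank (Mann-Whitney) statistic — equivalent to counting
#' concordant score/label pairs with ties worth one half — and selects the
#' decision cut-off maximising Youden's J = sensitivity + specificity - 1.
#' A pair is called positive when its score strictly exceeds the cut-off;
#' candidate cut-offs are midpoints between consecutive distinct scores
#' (plus the boundaries), and J-ties resolve to the smallest cut-off.
#'
#' @param scores Numeric vector of MaasPenn scores.
#' @param labels Binary (0/1 or logical) labels; both classes must occur.
#' @return One-row tibble: `score_cutoff`, `auc`, `sensitivity`,
#'   `specificity`, `false_alarm` (= 1 - specificity), `youden_j`,
#'   `n_positive`, `n_negative`.
#' @export
roc_select_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels lengths differ")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) rlang::abort("both classes must be present")

  auc <- rank_auc(scores, labels)
  u <- sort(unique(scores))
  cands <- c(min(u) - 1, (utils::head(u, -1) + u[-1]) / 2)
  sens <- spec <- numeric(length(cands))
  for (i in seq_along(cands)) {
    pos <- scores > cands[i]
    sens[i] <- sum(pos & labels == 1) / n1
    spec[i] <- sum(!pos & labels == 0) / n0
  }
  j <- sens + spec - 1
  best <- which.max(j)  # first max = smallest cut-off on ties
  tibble::tibble(
    score_cutoff = cands[best], auc = auc,
    sensitivity = sens[best], specificity = spec[best],
    false_alarm = 1 - spec[best], youden_j = j[best],
    n_positive = n1, n_negative = n0
  )
}

# Mann-Whitney AUC with midrank tie handling
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score cut-offs for a grid of reproducibility thresholds
#'
#' For each percentage threshold, labels every scenario 1 iff its percent
#' of reproducible features strictly exceeds the threshold and runs
#' [roc_select_cutoff()] on the scores. Thresholds at which only one class
#' occurs are returned as `NA` rows.
#'
#' @param scores Per-pair MaasPenn scores.
#' @param pct_reproducible Per-pair percentage of reproducible features.
#' @param thresholds Percent thresholds (default 10..90 by 10).
#' @return Tibble: `pct_threshold` plus the [roc_select_cutoff()] columns.
#' @export
threshold_analysis <- function(scores, pct_reproducible,
                               thresholds = seq(10, 90, by = 10)) {
  purrr::map_dfr(thresholds, function(th) {
    labels <- pct_reproducible > th
    if (all(labels) || !any(labels)) {
      return(tibble::tibble(pct_threshold = th, score_cutoff = NA_real_,
                            auc = NA_real_, sensitivity = NA_real_,
                            specificity = NA_real_, false_alarm = NA_real_,
                            youden_j = NA_real_,
                            n_positive = sum(labels),
                            n_negative = sum(!labels)))
    }
    dplyr::bind_cols(tibble::tibble(pct_threshold = th),
                     roc_select_cutoff(scores, labels))
  })
}

#' Published score cut-off table
#'
#' The packaged decision table for the published-weights screening
#' workflows: for each reproducibility threshold, the score cut-off
#' selected on the 31,375-pair phantom analysis together with its AUC
#' (95% CI), specificity, sensitivity and false-alarm rate. The
#' 70%-threshold row (cut-off 0.94) backs the default screening rule.
#'
#' @return Tibble with columns `pct_threshold`, `score_cutoff`, `auc`,
#'   `auc_ci_lower`, `auc_ci_upper`, `specificity`, `sensitivity`,
#'   `false_alarm`.
#' @export
published_cutoffs <- function() {
  tibble::tribble(
    ~pct_threshold, ~score_cutoff, ~auc, ~auc_ci_lower, ~auc_ci_upper,
    ~specificity, ~sensitivity, ~false_alarm,
    10, 0.75, 0.86, 0.855, 0.867, 0.81, 0.74, 0.19,
    20, 0.77, 0.85, 0.842, 0.851, 0.76, 0.77, 0.24,
    25, 0.80, 0.85, 0.843, 0.852, 0.80, 0.74, 0.20,
    30, 0.83, 0.86, 0.851, 0.860, 0.84, 0.73, 0.16,
    40, 0.85, 0.87, 0.868, 0.878, 0.81, 0.80, 0.19,
    50, 0.88, 0.90, 0.892, 0.904, 0.83, 0.85, 0.17,
    60, 0.88, 0.92, 0.910, 0.925, 0.79, 0.92, 0.21,
    70, 0.94, 0.96, 0.952, 0.966, 0.94, 0.89, 0.06,
    75, 0.95, 0.97, 0.967, 0.977, 0.95, 0.93, 0.05,
    80, 0.96, 0.98, 0.971, 0.983, 0.95, 0.95, 0.05,
    90, 0.98, 0.99, 0.982, 0.996, 0.97, 0.97, 0.03
  )
}

#' Robustness of the score over repeated train/validation splits
#'
#' Repeats the threshold ROC analysis over random 80/20 train/validation
#' splits of the scenarios: in each run the cut-off is selected on the
#' training split (Youden's J) and AUC, sensitivity and specificity are
#' evaluated on both splits at that cut-off. A run/threshold whose split
#' lacks both classes is returned as `NA`. Per-run seeds fan out from the
#' master seed by a counter (`seed + run`), so results are reproducible.
#'
#' @param scores Per-pair MaasPenn scores.
#' @param pct_reproducible Per-pair percent of reproducible features.
#' @param n_runs Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.8).
#' @param thresholds Percent thresholds (default 10..90 by 10).
#' @param seed Master seed.
#' @return Long tibble: `run`, `pct_threshold`, `set`
#'   (`"training"`/`"validation"`), `score_cutoff`, `auc`, `sensitivity`,
#'   `specificity`.
#' @export
robustness_runs <- function(scores, pct_reproducible, n_runs = 100,
                            train_frac = 0.8,
                            thresholds = seq(10, 90, by = 10), seed = 1L) {
  stopifnot(length(scores) == length(pct_reproducible))
  n <- length(scores)
  if (n < 10) rlang::abort("too few pairs to split")

  eval_set <- function(s, lab, cutoff) {
    n1 <- sum(lab); n0 <- sum(!lab)
    if (n1 == 0 || n0 == 0) {
      return(c(auc = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_))
    }
    pos <- s > cutoff
    c(auc = rank_auc(s, as.integer(lab)),
      sensitivity = sum(pos & lab) / n1,
      specificity = sum(!pos & !lab) / n0)
  }

  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    set.seed(seed + r)
    tr <- sample.int(n, size = round(train_frac * n))
    purrr::map_dfr(thresholds, function(th) {
      lab <- pct_reproducible > th
      lab_tr <- lab[tr]; lab_va <- lab[-tr]
      if (all(lab_tr) || !any(lab_tr)) {
        cut <- NA_real_
        m_tr <- m_va <- c(auc = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_)
      } else {
        cut <- roc_select_cutoff(scores[tr], lab_tr)$score_cutoff
        m_tr <- eval_set(scores[tr], lab_tr, cut)
        m_va <- eval_set(scores[-tr], lab_va, cut)
      }
      tibble::tibble(
        run = r, pct_threshold = th,
        set = c("training", "validation"),
        score_cutoff = cut,
        auc = c(m_tr["auc"], m_va["auc"]),
        sensitivity = c(m_tr["sensitivity"], m_va["sensitivity"]),
        specificity = c(m_tr["specificity"], m_va["specificity"])
      )
    })
  })
  runs
}
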