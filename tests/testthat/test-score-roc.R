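test_that("weight derivation normalises the top-k importances", {
  imp <- c(kernel = 48, slice_thickness = 33, pixel_spacing = 19,
           tube_current = 0.5, exposure = 0.1, exposure_time = 0.1,
           vendor = 0, model = 0)
  w <- derive_weights(imp, k = 3)
  expect_equal(as.numeric(w), c(0.48, 0.33, 0.19), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_identical(attr(w, "provenance"), "fitted")

  # invariant under uniform rescaling of importances
  w2 <- derive_weights(imp * 17.3, k = 3)
  expect_equal(as.numeric(w2), as.numeric(w), tolerance = 1e-12)

  # equal importances split evenly; zero importance gets zero weight
  expect_equal(as.numeric(derive_weights(c(kernel = 2, model = 2,
                                           vendor = 2), k = 3)),
               rep(1 / 3, 3))
  w3 <- derive_weights(c(kernel = 1, slice_thickness = 1,
                         pixel_spacing = 0), k = 3)
  expect_equal(unname(w3["pixel_spacing"]), 0)
  expect_error(derive_weights(c(kernel = 1), k = 3), "exceeds")
})

test_that("published weights and the score algebra match by hand", {
  w <- published_weights()
  expect_equal(sum(w), 1, tolerance = 1e-12)
  enc <- tibble::tibble(kernel = 1, slice_thickness = 1, pixel_spacing = 1)
  expect_equal(maaspenn_score(enc, w)$score, 1, tolerance = 1e-12)
  enc$kernel <- 0.5
  expect_equal(maaspenn_score(enc, w)$score, 0.76, tolerance = 1e-12)
  enc2 <- tibble::tibble(kernel = 1, slice_thickness = 0.5,
                         pixel_spacing = 1)
  expect_equal(maaspenn_score(enc2, w)$score, 0.835, tolerance = 1e-12)
  expect_error(maaspenn_score(tibble::tibble(kernel = 1), w), "lack")
})

test_that("the score is bounded, monotone and maximal only at full match", {
  set.seed(4)
  w <- published_weights()
  for (i in 1:50) {
    e <- tibble::tibble(kernel = runif(1), slice_thickness = runif(1),
                        pixel_spacing = runif(1))
    s <- maaspenn_score(e, w)$score
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s == 1, all(e == 1))
    # raising any retained component never lowers the score
    p <- sample(names(w), 1)
    e2 <- e
    e2[[p]] <- min(1, e[[p]] + runif(1, 0, 1 - e[[p]]))
    expect_gte(maaspenn_score(e2, w)$score, s - 1e-12)
  }
})

test_that("spearman correlation handles monotone, reversed, constant input", {
  s <- runif(20)
  expect_equal(score_outcome_correlation(s, 100 * plogis(s)), 1)
  expect_equal(score_outcome_correlation(s, -s^3), -1)
  expect_true(is.na(score_outcome_correlation(s, rep(1, 20))))
  expect_error(score_outcome_correlation(1:3, 1:4), "lengths differ")
})

test_that("ROC cut-off selection is exact on separable data and null data", {
  # perfect separation: AUC 1, sens = spec = 1
  sc <- c(runif(30, 0, 0.4), runif(30, 0.6, 1))
  lab <- rep(c(0, 1), each = 30)
  r <- roc_select_cutoff(sc, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$false_alarm, 0)
  expect_true(r$score_cutoff > 0.4 && r$score_cutoff < 0.6)

  # labels independent of scores: AUC ~ 0.5 at n = 5000
  set.seed(10)
  sc2 <- runif(5000); lab2 <- rbinom(5000, 1, 0.5)
  expect_equal(roc_select_cutoff(sc2, lab2)$auc, 0.5, tolerance = 0.03)

  expect_error(roc_select_cutoff(runif(5), rep(1, 5)), "both classes")
})

test_that("rank-statistic AUC equals the exhaustive concordance oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    sc <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_select_cutoff(sc, lab)$auc, brute_auc(sc, lab),
                 tolerance = 1e-12)
  }
})

test_that("selected cut-offs agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- c(rnorm(100, 0.4, 0.1), rnorm(100, 0.7, 0.1))
  lab <- rep(c(0, 1), each = 100)
  mine <- roc_select_cutoff(sc, lab)
  ref <- pROC::roc(lab, sc, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  best <- pROC::coords(ref, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(mine$sensitivity + mine$specificity,
               best$sensitivity[1] + best$specificity[1], tolerance = 1e-9)
})

test_that("threshold grid labels strictly above and flags one-class rows", {
  pct <- c(5, 15, 30, 60, 95)
  sc <- c(0.3, 0.5, 0.7, 0.9, 1.0)
  tab <- threshold_analysis(sc, pct, thresholds = c(10, 50, 90))
  expect_equal(tab$n_positive, c(4L, 2L, 1L))
  # threshold exactly at a pct value: strict >, so 95 is NOT above 95
  tab2 <- threshold_analysis(sc, pct, thresholds = 95)
  expect_equal(tab2$n_positive, 0L)
  expect_true(is.na(tab2$auc))
})

test_that("published cut-off table is internally consistent", {
  tab <- published_cutoffs()
  expect_equal(nrow(tab), 11)
  expect_equal(tab$false_alarm, 1 - tab$specificity, tolerance = 1e-12)
  expect_equal(tab$score_cutoff[tab$pct_threshold == 70], 0.94)
  expect_true(all(diff(tab$score_cutoff) >= 0))
})

test_that("robustness runs are seeded, reproducible and near-degenerate
           when the outcome is noiseless", {
  set.seed(2)
  sc <- runif(200)
  pct <- 100 * sc  # deterministic monotone outcome
  r1 <- robustness_runs(sc, pct, n_runs = 20, seed = 7)
  r2 <- robustness_runs(sc, pct, n_runs = 20, seed = 7)
  expect_identical(r1, r2)
  # deterministic outcome: every computed AUC is exactly 1
  expect_true(all(r1$auc[!is.na(r1$auc)] == 1))
  # both sets present for every run/threshold
  expect_equal(nrow(r1), 20 * 9 * 2)
})

test_that("random forest fit is deterministic and finds no signal in noise", {
  set.seed(31)
  enc <- tibble::as_tibble(matrix(runif(300 * 8), 300, 8,
                                  dimnames = list(NULL, scan_parameters())))
  enc$pct_reproducible <- runif(300, 0, 100)
  f1 <- fit_reproducibility_rf(enc, n_trees = 100, seed = 5)
  f2 <- fit_reproducibility_rf(enc, n_trees = 100, seed = 5)
  expect_identical(f1$importance, f2$importance)
  expect_lt(f1$var_explained, 15)  # independent outcome: ~0 explained
  expect_error(fit_reproducibility_rf(dplyr::mutate(enc,
                                                    pct_reproducible = 50)),
               "constant")
})
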