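# simulate two batches with known location/scale effects on the
# standardised scale: batch 2 is z + gamma_g, scale delta_g
sim_batches <- function(n = 160, g = 60, seed = 1,
                        gamma_mean = 1.5, gamma_sd = 0.3, delta = 1.5) {
  set.seed(seed)
  mu <- runif(g, 50, 150)
  sigma <- runif(g, 5, 20)
  gamma <- rnorm(g, gamma_mean, gamma_sd)
  b1 <- sweep(sweep(matrix(rnorm(n * g), n, g), 2, sigma, `*`), 2, mu, `+`)
  b2 <- matrix(rnorm(n * g), n, g) * delta
  b2 <- sweep(b2, 2, sigma, `*`)
  b2 <- sweep(b2, 2, mu + gamma * sigma, `+`)
  x <- rbind(b1, b2)
  colnames(x) <- paste0("f", seq_len(g))
  list(x = x, batch = rep(c("b1", "b2"), each = n),
       gamma = gamma, delta = delta, mu = mu, sigma = sigma)
}

test_that("fit_combat validates its inputs", {
  s <- sim_batches(n = 20, g = 5)
  expect_error(fit_combat(s$x, rep("b1", 40)), "at least 2 batches")
  expect_error(fit_combat(s$x[c(1, 21), ], s$batch[c(1, 21)]),
               "at least 2 samples")
})

test_that("identical batches give near-zero additive, near-unit scale", {
  set.seed(5)
  x <- matrix(rnorm(80 * 10, 100, 10), 80, 10)
  fit <- fit_combat(x, rep(c("a", "b"), each = 40))
  # no batch effect: shrunken estimates hug 0 / 1
  expect_lt(max(abs(fit$gamma_star)), 0.4)
  expect_lt(max(abs(fit$delta2_star - 1)), 0.5)
  # adjustment is a near no-op
  adj <- apply_combat(fit, x, rep(c("a", "b"), each = 40))
  expect_equal(dim(adj), dim(x))
  expect_lt(max(abs(adj - x)) / sd(x), 0.35)
})

test_that("known batch effects are recovered and removed", {
  s <- sim_batches()
  fit <- fit_combat(s$x, s$batch)
  # standardisation uses the pooled sigma, so compare on that scale
  sig <- sqrt(fit$sigma2)
  gamma_gap <- fit$gamma_star["b2", ] - fit$gamma_star["b1", ]
  gamma_true <- s$gamma * s$sigma / sig
  expect_lt(mean(abs(gamma_gap - gamma_true) / abs(gamma_true)), 0.10)
  delta_ratio <- sqrt(fit$delta2_star["b2", ] / fit$delta2_star["b1", ])
  expect_lt(mean(abs(delta_ratio - s$delta) / s$delta), 0.10)

  # location adjustment: post-hoc batch mean gap under 3 standard errors
  adj <- apply_combat(fit, s$x, s$batch)
  m1 <- colMeans(adj[s$batch == "b1", ])
  m2 <- colMeans(adj[s$batch == "b2", ])
  pooled_sd <- apply(adj, 2, sd)
  se <- pooled_sd * sqrt(2 / 160)
  expect_true(all(abs(m2 - m1) < 3 * se))
})

test_that("harmonization preserves shape and is near-idempotent", {
  s <- sim_batches(n = 60, g = 20, seed = 3)
  fit <- fit_combat(s$x, s$batch)
  once <- apply_combat(fit, s$x, s$batch)
  fit2 <- fit_combat(once, s$batch)
  twice <- apply_combat(fit2, once, s$batch)
  expect_equal(dim(once), dim(s$x))
  expect_identical(colnames(once), colnames(s$x))
  # a refit re-estimates the EB priors on adjusted data, so a small
  # residual shrinkage adjustment remains
  expect_lt(max(abs(twice - once)) / sd(once), 0.1)
  expect_error(apply_combat(fit, s$x, rep("mystery", 120)), "unknown batch")
})

test_that("zero-variance features pass through unadjusted", {
  s <- sim_batches(n = 30, g = 6, seed = 9)
  s$x[, 3] <- 7
  fit <- fit_combat(s$x, s$batch)
  expect_identical(fit$zero_var, "f3")
  adj <- apply_combat(fit, s$x, s$batch)
  expect_equal(adj[, 3], s$x[, 3])
})

test_that("mean-shifted features regain concordance after harmonization", {
  set.seed(11)
  v <- matrix(rnorm(160 * 4, 100, 20), 160, 4)
  ta <- make_table(v, scan_id = "a")
  shift <- v
  shift[, 2] <- shift[, 2] + 60  # pure location batch effect
  tb <- make_table(shift + rnorm(640, 0, 0.5), scan_id = "b")
  before <- pair_ccc(ta, tb)
  expect_false(before$reproducible[2])
  hp <- harmonize_pair(ta, tb)
  after <- pair_ccc(hp$a, hp$b)
  expect_gt(after$ccc[2], 0.95)
  # pipeline invariant: harmonized count >= raw count
  expect_gte(sum(after$reproducible), sum(before$reproducible))
})

test_that("parametric EB agrees with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  s <- sim_batches(n = 40, g = 25, seed = 21)
  fit <- fit_combat(s$x, s$batch)
  mine <- apply_combat(fit, s$x, s$batch)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(s$x), batch = s$batch, prior.plots = FALSE)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("models serialize to JSON and back", {
  s <- sim_batches(n = 30, g = 8, seed = 2)
  fit <- fit_combat(s$x, s$batch)
  path <- withr::local_tempfile(fileext = ".json")
  write_combat_model(fit, path)
  back <- read_combat_model(path)
  adj1 <- apply_combat(fit, s$x, s$batch)
  adj2 <- apply_combat(back, s$x, s$batch)
  expect_equal(adj1, adj2, tolerance = 1e-12)
})

test_that("non-parametric mode also removes location shifts", {
  s <- sim_batches(n = 40, g = 12, seed = 13)
  fit <- fit_combat(s$x, s$batch, parametric = FALSE)
  adj <- apply_combat(fit, s$x, s$batch)
  gap_before <- colMeans(s$x[s$batch == "b2", ]) -
    colMeans(s$x[s$batch == "b1", ])
  gap_after <- colMeans(adj[s$batch == "b2", ]) -
    colMeans(adj[s$batch == "b1", ])
  expect_lt(mean(abs(gap_after)), 0.3 * mean(abs(gap_before)))
})
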