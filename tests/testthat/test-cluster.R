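test_that("point-wise paired t matches the textbook statistic", {
  set.seed(81)
  a <- matrix(rnorm(50), 10, 5)
  b <- matrix(rnorm(50), 10, 5)
  ours <- pointwise_paired_t(a, b)
  oracle <- vapply(1:5, function(j) unname(t.test(a[, j], b[, j],
                                                  paired = TRUE)$statistic),
                   numeric(1))
  expect_equal(ours, oracle, tolerance = 1e-10)
  expect_equal(pointwise_paired_t(a, a), rep(0, 5))
  # constant positive difference with tiny jitter: large positive t
  d <- a + 1 + matrix(rnorm(50, sd = 1e-3), 10, 5)
  expect_true(all(pointwise_paired_t(d, a) > 50))
  # zero-variance nonzero difference: flagged infinite (supra-threshold)
  expect_equal(pointwise_paired_t(a + 2, a), rep(Inf, 5))
})

test_that("point-wise correlation matches direct computation", {
  set.seed(83)
  x <- matrix(rnorm(60), 10, 6)
  pc <- pointwise_correlation(x, 2 * x + 1)
  expect_equal(pc$r, rep(1, 6), tolerance = 1e-12)
  y <- matrix(rnorm(60), 10, 6)
  pc2 <- pointwise_correlation(x, y)
  oracle <- vapply(1:6, function(j) cor(x[, j], y[, j]), numeric(1))
  expect_equal(pc2$r, oracle, tolerance = 1e-12)
  t_oracle <- oracle * sqrt((10 - 2) / (1 - oracle^2))
  expect_equal(pc2$t, t_oracle, tolerance = 1e-12)
  # six printed pairs, correlation computed by hand from sums:
  xf <- c(1, 2, 3, 4, 5, 6); yf <- c(2, 1, 4, 3, 7, 8)
  num <- sum(xf * yf) - 6 * mean(xf) * mean(yf)
  den <- sqrt((sum(xf^2) - 6 * mean(xf)^2) * (sum(yf^2) - 6 * mean(yf)^2))
  pc3 <- pointwise_correlation(cbind(xf, xf), cbind(yf, yf))
  expect_equal(pc3$r, rep(num / den, 2), tolerance = 1e-12)
  # constant column: undefined, sub-threshold
  pc4 <- pointwise_correlation(matrix(1, 10, 1), y[, 1, drop = FALSE])
  expect_true(is.na(pc4$r) && pc4$t == 0)
})

test_that("null correlations exceed the critical value at the nominal rate", {
  set.seed(85)
  n <- 56; nf <- 2000
  x <- matrix(rnorm(n * nf), n, nf)
  y <- matrix(rnorm(n * nf), n, nf)
  pc <- pointwise_correlation(x, y)
  t_crit <- qt(0.975, df = n - 2)
  frac <- mean(abs(pc$t) > t_crit)
  se <- sqrt(0.05 * 0.95 / nf)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("cluster formation and mass match an independent implementation", {
  stat <- c(0.5, 3, 4, 0.2, -3, -5, -2.5, 0.1, 2.7)
  thr <- 2.1
  cl <- dyadcoh:::cluster_table(stat, thr, freqs = seq_along(stat) / 5)
  # hand enumeration: runs {2,3}, {5,6,7}, {9}
  expect_equal(cl$freq_lo, c(2, 5, 9) / 5)
  expect_equal(cl$freq_hi, c(3, 7, 9) / 5)
  expect_equal(cl$mass, c(7, 10.5, 2.7))
  expect_equal(dyadcoh:::max_cluster_mass(stat, thr), 10.5)
  expect_equal(dyadcoh:::max_cluster_mass(rep(0.1, 9), thr), 0)
})

test_that("sub-threshold series yield no clusters and add-one p-values", {
  set.seed(87)
  a <- matrix(rnorm(80, sd = 1), 8, 10)
  res <- cluster_permutation(a, a + matrix(rnorm(80, sd = 1e-6), 8, 10),
                             n_perm = 99, seed = 3)
  if (nrow(res$clusters) > 0) {
    expect_true(all(res$clusters$p_value >= 1 / 100))
  }
  sub <- cluster_permutation(matrix(rnorm(50, sd = 1), 10, 5),
                             matrix(rnorm(50, sd = 1), 10, 5),
                             n_perm = 49, seed = 4)
  expect_true(all(abs(sub$stat_series$stat) < 20))
  expect_true(all(sub$clusters$p_value > 0))
})

test_that("swapping the contrast direction preserves cluster p-values", {
  set.seed(89)
  a <- matrix(rnorm(120), 12, 10) + rep(c(0, 0, 1.2, 1.2, 0, 0, 0, 0, 0, 0),
                                        each = 12)
  b <- matrix(rnorm(120), 12, 10)
  r1 <- cluster_permutation(a, b, n_perm = 300, seed = 11)
  r2 <- cluster_permutation(b, a, n_perm = 300, seed = 11)
  expect_equal(r1$stat_series$stat, -r2$stat_series$stat, tolerance = 1e-12)
  expect_equal(r1$clusters$mass, r2$clusters$mass, tolerance = 1e-12)
  expect_equal(r1$clusters$p_value, r2$clusters$p_value)
})

test_that("the sign-flip null matches exhaustive enumeration at n = 5", {
  set.seed(91)
  n <- 5; nf <- 12
  d <- matrix(rnorm(n * nf), n, nf) +
    rep(c(rep(2.5, 4), rep(0, nf - 4)), each = n)
  a <- d; b <- matrix(0, n, nf)
  thr <- qt(0.975, df = n - 1)
  # exhaustive oracle over all 2^5 sign patterns, written independently:
  # per pattern, recompute the paired t series and its max cluster mass
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  oracle_max <- apply(patterns, 1, function(s) {
    ds <- d * s
    ts <- colMeans(ds) / (apply(ds, 2, sd) / sqrt(n))
    supra <- abs(ts) > thr
    if (!any(supra)) return(0)
    best <- 0; run <- 0
    for (j in seq_len(nf)) {
      run <- if (supra[j]) run + abs(ts[j]) else 0
      best <- max(best, run)
    }
    best
  })
  obs_mass <- dyadcoh:::max_cluster_mass(pointwise_paired_t(a, b), thr)
  p_exact <- mean(oracle_max >= obs_mass - 1e-12)
  res <- cluster_permutation(a, b, n_perm = 4000, seed = 13,
                             p_convention = "raw")
  # Monte-Carlo permutation masses are draws from the exhaustive set
  expect_true(all(vapply(res$null_max, function(m)
    any(abs(oracle_max - m) < 1e-8), logical(1))))
  p_mc <- res$clusters$p_value[which.max(res$clusters$mass)]
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})
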