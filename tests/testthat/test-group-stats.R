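# Voxelwise Hotelling T-squared maps, the Shapiro-Wilk screen, BY-FDR and
# thresholding.

gauss_fields <- function(n, shape = c(22, 22, 22), shift = 0, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- array(rnorm(prod(shape) * 3), c(shape, 3))
    a[, , , 1] <- a[, , , 1] + shift
    velocity_field(a)
  })
}

full_mask <- function(shape = c(22, 22, 22)) scalar_volume(array(1, shape))

test_that("T2 p-values are calibrated under the Gaussian null", {
  g1 <- gauss_fields(20, seed = 42)
  g2 <- gauss_fields(20, seed = 43)
  sm <- hotelling_t2_map(g1, g2, full_mask())
  p <- as.vector(unclass(sm$p))
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.02)
  expect_equal(sm$n_ridged, 0)
})

test_that("T2 power for a 1-sd mean shift matches the noncentral-F value", {
  g1 <- gauss_fields(20, seed = 42)
  g2 <- gauss_fields(20, shift = 1, seed = 44)
  sm <- hotelling_t2_map(g1, g2, full_mask())
  rate <- mean(as.vector(unclass(sm$p)) < 0.05)
  # exact power: F(3, 36) with noncentrality n1*n2/(n1+n2) * delta^2 = 10
  theo <- 1 - pf(qf(0.95, 3, 36), 3, 36, ncp = 10)
  expect_equal(rate, theo, tolerance = 0.05)
  expect_gt(rate, 3 * 0.05)   # far above the null rate
})

test_that("identical groups give T2 = 0 and p = 1", {
  g <- gauss_fields(6, shape = c(6, 6, 6))
  sm <- hotelling_t2_map(g, g, full_mask(c(6, 6, 6)))
  expect_equal(max(unclass(sm$t2)), 0)
  expect_equal(min(unclass(sm$p)), 1)
})

test_that("the F-transform p-value agrees with a permutation oracle", {
  shape <- c(5, 5, 5)
  g1 <- gauss_fields(20, shape, seed = 31)
  g2 <- gauss_fields(20, shape, shift = 0.4, seed = 32)
  sm <- hotelling_t2_map(g1, g2, full_mask(shape))
  t2_of <- function(a, b) {
    d <- rowMeans(a) - rowMeans(b)
    S <- (stats::cov(t(a)) * (ncol(a) - 1) + stats::cov(t(b)) * (ncol(b) - 1)) /
         (ncol(a) + ncol(b) - 2)
    (ncol(a) * ncol(b) / (ncol(a) + ncol(b))) * drop(t(d) %*% solve(S, d))
  }
  set.seed(99)
  vox <- cbind(sample(5, 10, TRUE), sample(5, 10, TRUE), sample(5, 10, TRUE))
  for (k in seq_len(nrow(vox))) {
    x1 <- sapply(g1, function(v) unclass(v)[vox[k, 1], vox[k, 2], vox[k, 3], ])
    x2 <- sapply(g2, function(v) unclass(v)[vox[k, 1], vox[k, 2], vox[k, 3], ])
    X <- cbind(x1, x2)
    obs <- t2_of(x1, x2)
    perm <- replicate(5000, {
      idx <- sample(40, 20)
      t2_of(X[, idx], X[, -idx])
    })
    p_perm <- mean(perm >= obs)
    expect_lt(abs(unclass(sm$p)[vox[k, 1], vox[k, 2], vox[k, 3]] - p_perm),
              0.02)
  }
})

test_that("T2 is invariant under a common invertible linear transform", {
  shape <- c(4, 4, 4)
  g1 <- gauss_fields(10, shape, seed = 3)
  g2 <- gauss_fields(10, shape, shift = 0.5, seed = 4)
  A <- matrix(c(2, 0.3, -0.1, 0, 1.5, 0.2, 0.1, 0, 0.8), 3, 3, byrow = TRUE)
  tf <- function(v) {
    d <- unclass(v); out <- d
    for (i in 1:3)
      out[, , , i] <- A[i, 1] * d[, , , 1] + A[i, 2] * d[, , , 2] +
                      A[i, 3] * d[, , , 3]
    velocity_field(out)
  }
  s1 <- hotelling_t2_map(g1, g2, full_mask(shape))
  s2 <- hotelling_t2_map(lapply(g1, tf), lapply(g2, tf), full_mask(shape))
  expect_equal(unclass(s1$t2), unclass(s2$t2), tolerance = 1e-6)
})

test_that("group sizes too small for the F reference are rejected", {
  g <- gauss_fields(2, shape = c(4, 4, 4))
  expect_error(hotelling_t2_map(g, g[1], full_mask(c(4, 4, 4))), "too small")
})

test_that("Shapiro screen passes Gaussian data at the theoretical rate and flags heavy tails", {
  shape <- c(12, 12, 12)
  g <- gauss_fields(30, shape, seed = 7)
  sw <- voxelwise_shapiro(g, full_mask(shape))
  # all three components must pass at alpha = 0.05: expectation 0.95^3
  expect_equal(sw$fraction, 0.95^3, tolerance = 0.03)

  set.seed(8)
  heavy <- lapply(1:30, function(i)
    velocity_field(array(stats::rt(prod(shape) * 3, df = 2), c(shape, 3))))
  swh <- voxelwise_shapiro(heavy, full_mask(shape))
  expect_lt(swh$fraction, 0.5 * sw$fraction)

  # constant components are degenerate but counted as passing
  const <- lapply(1:3, function(i) zero_velocity(c(4, 4, 4)))
  swc <- voxelwise_shapiro(const, full_mask(c(4, 4, 4)))
  expect_equal(swc$fraction, 1)
  expect_gt(swc$n_degenerate, 0)
})

test_that("BY correction reproduces the hand-worked example and dominates BH", {
  expect_equal(fdr_correct(0.01), 0.01)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  set.seed(23)
  for (i in 1:5) {
    p <- runif(50)
    expect_true(all(fdr_correct(p, "BY") >= fdr_correct(p, "BH") - 1e-12))
    expect_true(all(fdr_correct(p, "BY") >= p - 1e-12))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("threshold_map behaves at the extremes and is monotone in the threshold", {
  shape <- c(6, 6, 6)
  g1 <- gauss_fields(10, shape, seed = 3)
  g2 <- gauss_fields(10, shape, shift = 2, seed = 4)
  sm <- stat_map_fdr(hotelling_t2_map(g1, g2, full_mask(shape)))
  all_q1 <- sm; all_q1$q <- scalar_volume(array(1, shape))
  expect_equal(sum(unclass(threshold_map(all_q1, 0.001))), 0)
  expect_equal(unclass(threshold_map(sm, 1)), unclass(full_mask(shape)),
               ignore_attr = TRUE)
  m1 <- unclass(threshold_map(sm, 0.001))
  m2 <- unclass(threshold_map(sm, 0.01))
  expect_true(all(m2[m1 == 1] == 1))   # larger threshold => superset
  # q >= p voxelwise
  expect_true(all(unclass(sm$q) >= unclass(sm$p) - 1e-12, na.rm = TRUE))
})
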