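# Field algebra: exponential map, composition, warping, smoothing, BCH and
# the differential operators.

test_that("exp_svf handles the identity and rejects bad input", {
  v0 <- zero_velocity(c(8, 8, 8))
  phi <- exp_svf(v0, 1)
  expect_equal(max(abs(unclass(phi))), 0)
  expect_error(exp_svf(velocity_field(array(1000, c(8, 8, 8, 3))),
                       t = 1e6), "too large")
})

test_that("exp_svf of a linear-generator SVF matches the matrix-exponential oracle", {
  skip_if_not_installed("pracma")
  A_list <- list(
    matrix(c(0.05, -0.08, 0, 0.08, 0.05, 0, 0, 0, -0.04), 3, 3, byrow = TRUE),
    matrix(c(-0.06, 0, 0.03, 0, 0.05, 0, -0.02, 0, 0.04), 3, 3, byrow = TRUE))
  for (A in A_list) {
    v <- linear_svf(A, 24L)
    phi <- exp_svf(v, 1)
    u_true <- affine_displacement(pracma::expm(A), 24L)
    err <- vec_mag(unclass(phi) - u_true)
    expect_lt(max(err[interior_idx(c(24, 24, 24), 5L)]), 1e-3)
  }
})

test_that("exp_svf satisfies the one-parameter semigroup property", {
  vr <- random_smooth_svf(32, sigma = 4, max_norm = 3, seed = 11)
  whole <- exp_svf(vr, 1)
  halves <- compose(exp_svf(vr, 0.3), exp_svf(vr, 0.7))
  d <- vec_mag(unclass(halves) - unclass(whole))
  expect_lt(max(d[interior_idx(c(32, 32, 32))]), 1e-2)
})

test_that("Exp(v) and Exp(-v) are inverse to each other", {
  for (seed in c(11L, 29L)) {
    vr <- random_smooth_svf(32, sigma = 4, max_norm = 3, seed = seed)
    cc <- compose(exp_svf(vr, 1), exp_svf(vr, -1))
    expect_lt(max(vec_mag(cc)[interior_idx(c(32, 32, 32))]), 0.1)
  }
})

test_that("compose has identity elements and adds constant translations", {
  set.seed(4)
  u <- array(rnorm(6 * 6 * 6 * 3, sd = 0.3), c(6, 6, 6, 3))
  phi <- deformation_field(u)
  id <- identity_deformation(c(6, 6, 6))
  expect_equal(unclass(compose(phi, id)), u, tolerance = 1e-12,
               ignore_attr = TRUE)
  # identity sampled at phi-mapped points stays zero displacement
  expect_equal(unclass(compose(id, phi)), u, tolerance = 1e-12,
               ignore_attr = TRUE)

  t1 <- deformation_field(array(rep(c(1, 0, 0), each = 7^3), c(7, 7, 7, 3)))
  t2 <- deformation_field(array(rep(c(0, 2, 0), each = 7^3), c(7, 7, 7, 3)))
  comp <- unclass(compose(t2, t1))
  inner <- interior_idx(c(7, 7, 7), 2L)
  expect_equal(unique(comp[, , , 1][inner]), 1)
  expect_equal(unique(comp[, , , 2][inner]), 2)
  expect_equal(unique(comp[, , , 3][inner]), 0)
  expect_error(compose(phi, t1), "shape")
})

test_that("warp_image implements the pull-back convention", {
  img <- array(0, c(5, 5, 5)); img[2, 3, 3] <- 1   # unit impulse
  vol <- scalar_volume(img)
  expect_equal(unclass(warp_image(vol, identity_deformation(c(5, 5, 5)))), img,
               ignore_attr = TRUE)
  const <- scalar_volume(array(0.7, c(5, 5, 5)))
  shift <- deformation_field(array(rep(c(2, 0, 0), each = 5^3), c(5, 5, 5, 3)))
  expect_equal(unique(as.vector(unclass(warp_image(const, shift)))), 0.7)
  # pull-back: out(x) = img(x + 2 e1), so the impulse lands at x = 2 - 2 ... i.e.
  # output voxel (4,3,3) reads img(6,3,3)->clamped; voxel (0,...) out of grid.
  out <- unclass(warp_image(vol, shift))
  hand <- array(0, c(5, 5, 5))
  for (x in 1:5) hand[x, 3, 3] <- img[min(x + 2, 5), 3, 3]
  expect_equal(out[, 3, 3], hand[, 3, 3])
})

test_that("gaussian_smooth_field preserves constants and matches a direct convolution", {
  const <- velocity_field(array(rep(c(1, -2, 3), each = 9^3), c(9, 9, 9, 3)))
  sm <- gaussian_smooth_field(const, 2)
  expect_equal(unclass(sm), unclass(const), tolerance = 1e-12)
  expect_identical(gaussian_smooth_field(const, 0), const)
  expect_error(gaussian_smooth_field(const, -1), "sigma")

  # impulse response equals the separable outer-product kernel
  n <- 17L; sigma <- 1.5
  f <- array(0, c(n, n, n, 3)); f[9, 9, 9, 1] <- 1
  sm <- unclass(gaussian_smooth_field(velocity_field(f), sigma))
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  oracle <- outer(outer(k, k), k)   # (2r+1)^3 kernel centered at impulse
  got <- sm[(9 - r):(9 + r), (9 - r):(9 + r), (9 - r):(9 + r), 1]
  expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(max(abs(sm[, , , 2:3])), 0)
})

test_that("smoothing commutes with whole-voxel translation in the interior", {
  set.seed(9)
  n <- 16L
  f <- array(rnorm(n^3 * 3), c(n, n, n, 3))
  fshift <- f[c(2:n, n), , , , drop = FALSE]          # translate by -1 along x
  s1 <- unclass(gaussian_smooth_field(velocity_field(f), 1.2))
  s2 <- unclass(gaussian_smooth_field(velocity_field(fshift), 1.2))
  inner <- 7:10
  expect_equal(s1[inner + 1, inner, inner, ], s2[inner, inner, inner, ],
               tolerance = 1e-10)
})

test_that("bch_compose reduces to addition for commuting fields and is 2nd-order accurate", {
  v <- random_smooth_svf(16, sigma = 3, max_norm = 0.5, seed = 5)
  z <- zero_velocity(c(16, 16, 16))
  expect_equal(unclass(bch_compose(v, z)), unclass(v), tolerance = 1e-12)
  c1 <- velocity_field(array(rep(c(0.5, 1, -1), each = 16^3), c(16, 16, 16, 3)))
  c2 <- velocity_field(array(rep(c(-1, 2, 0.5), each = 16^3), c(16, 16, 16, 3)))
  expect_equal(unclass(bch_compose(c1, c2)),
               unclass(c1) + unclass(c2), tolerance = 1e-12)
  expect_error(bch_compose(v, z, order = 3), "order")

  # endpoint discrepancy of Exp(BCH(v,u)) vs Exp(v) o Exp(u): the 2nd-order
  # term must cut the order-1 error substantially, and the remainder must
  # shrink superlinearly when both fields are halved (the ideal 8x cubic rate
  # is masked by the trilinear interpolation error of the composition oracle)
  vv <- random_smooth_svf(24, sigma = 5, max_norm = 2, seed = 5)
  uu <- random_smooth_svf(24, sigma = 5, max_norm = 2, seed = 6)
  endpoint_gap <- function(scale, order) {
    vs <- velocity_field(unclass(vv) * scale)
    us <- velocity_field(unclass(uu) * scale)
    direct <- compose(exp_svf(vs, 1, 6L), exp_svf(us, 1, 6L))
    viabch <- exp_svf(bch_compose(vs, us, order), 1, 6L)
    inner <- interior_idx(c(24, 24, 24), 5L)
    mean(vec_mag(unclass(direct) - unclass(viabch))[inner])
  }
  expect_gt(endpoint_gap(1, 1L) / endpoint_gap(1, 2L), 4)
  expect_gt(endpoint_gap(1, 2L) / endpoint_gap(0.5, 2L), 3)
})

test_that("jacobian_determinant matches closed forms", {
  id <- identity_deformation(c(10, 10, 10))
  expect_equal(as.vector(unclass(jacobian_determinant(id))), rep(1, 1000))
  B <- diag(3) * 1.1
  phi <- deformation_field(affine_displacement(B, 16L))
  jd <- unclass(jacobian_determinant(phi))
  expect_equal(unique(round(jd[interior_idx(c(16, 16, 16), 2L)], 10)), 1.331)
  # Exp of a smooth small field stays orientation-preserving
  v <- random_smooth_svf(16, sigma = 3, max_norm = 1.5, seed = 8)
  jd2 <- unclass(jacobian_determinant(exp_svf(v, 1)))
  expect_gt(min(jd2[interior_idx(c(16, 16, 16), 1L)]), 0)
})

test_that("divergence matches analytic values and the flux oracle", {
  cst <- velocity_field(array(rep(c(1, 2, 3), each = 12^3), c(12, 12, 12, 3)))
  expect_equal(max(abs(unclass(divergence(cst))[interior_idx(c(12, 12, 12), 1L)])), 0)
  radial <- linear_svf(diag(3), 16L)
  dv <- unclass(divergence(radial))
  expect_equal(unique(round(dv[interior_idx(c(16, 16, 16), 1L)], 10)), 3)

  # discrete divergence theorem on an interior box
  v <- random_smooth_svf(16, sigma = 3, max_norm = 2, seed = 12)
  vd <- unclass(v)
  box <- 5:12
  vol_int <- sum(unclass(divergence(v))[box, box, box])
  flux <- function(comp, axis) {
    hi <- ifelse(axis == 1, 12, ifelse(axis == 2, 12, 12))
    lo <- 5
    # midpoint surface flux via central-difference-consistent face averages
    if (axis == 1) sum((vd[13, box, box, 1] + vd[12, box, box, 1]) / 2) -
                   sum((vd[4, box, box, 1] + vd[5, box, box, 1]) / 2)
    else if (axis == 2) sum((vd[box, 13, box, 2] + vd[box, 12, box, 2]) / 2) -
                        sum((vd[box, 4, box, 2] + vd[box, 5, box, 2]) / 2)
    else sum((vd[box, box, 13, 3] + vd[box, box, 12, 3]) / 2) -
         sum((vd[box, box, 4, 3] + vd[box, box, 5, 3]) / 2)
  }
  surf <- flux(1, 1) + flux(2, 2) + flux(3, 3)
  expect_lt(abs(vol_int - surf) / max(abs(surf), 1e-9), 0.05)
})

test_that("geodesic_length matches straight-line and arc-length oracles", {
  z <- zero_velocity(c(8, 8, 8))
  expect_equal(max(abs(unclass(geodesic_length(z)))), 0)
  cst <- velocity_field(array(rep(c(3, 4, 0), each = 12^3), c(12, 12, 12, 3)))
  gl <- unclass(geodesic_length(cst))
  expect_equal(unique(round(gl[interior_idx(c(12, 12, 12), 1L)], 8)), 5)
  # rigid rotation generator: GL ~ r * theta
  n <- 33L; ctr <- 17; theta <- 0.3
  pos <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  v <- array(0, c(n, n, n, 3))
  v[, , , 1] <- array(-theta * (pos$y - ctr), c(n, n, n))
  v[, , , 2] <- array(theta * (pos$x - ctr), c(n, n, n))
  gl <- unclass(geodesic_length(velocity_field(v), 64L))
  r <- 8
  expect_equal(gl[ctr + r, ctr, ctr], r * theta, tolerance = 0.02 * r * theta)
})

test_that("field_squared_norm sums squared magnitudes over the mask", {
  z <- zero_velocity(c(6, 6, 6))
  expect_equal(field_squared_norm(z), 0)
  f <- array(0, c(6, 6, 6, 3)); f[2, 3, 4, ] <- c(1, 2, 2)
  expect_equal(field_squared_norm(velocity_field(f)), 9)
  set.seed(15)
  g <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  vf <- velocity_field(g)
  expect_equal(field_squared_norm(vf), sum(g^2))
  m <- array(0, c(6, 6, 6)); m[1:3, , ] <- 1
  brute <- sum((g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)[m > 0])
  expect_equal(field_squared_norm(vf, scalar_volume(m)), brute)
  expect_error(field_squared_norm(vf, scalar_volume(array(0.5, c(6, 6, 6)))),
               "binary")
})
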