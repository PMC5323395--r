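# Field algebra on discrete stationary velocity fields (SVFs): exponential map,
# composition, warping, smoothing, BCH, and differential operators. All
# displacements are in voxel units; derivatives use central differences with
# one-sided differences on the boundary faces; interpolation is trilinear with
# clamp-to-edge boundary handling.

#' Exponential map of a stationary velocity field
#'
#' Integrates the flow of `v` for virtual time `t` by scaling and squaring:
#' `v * t` is scaled by `2^-K`, turned into a near-identity deformation, and
#' self-composed `K` times. The near-identity step uses the second-order
#' expansion `u = w + (Dw) w / 2` of the flow (with `Dw` the Jacobian of the
#' scaled field by central differences) rather than the bare Euler step, so
#' the overall error is second order in the scaled field. `K` is chosen
#' automatically so that the maximum displacement after scaling is below half
#' a voxel, which keeps each composition step well inside the linear regime of
#' the interpolator.
#'
#' @param v a [velocity_field()].
#' @param t virtual time parameter; `t = 1` gives the full deformation,
#'   `t = -1` its inverse flow.
#' @param squaring_steps integer number of squaring steps, or `"auto"`.
#' @return A [deformation_field()] representing `Exp(v * t)`.
#' @export
exp_svf <- function(v, t = 1, squaring_steps = "auto") {
  v <- as_velocity(v)
  if (!is.finite(t)) stop("exp_svf: t must be finite")
  w <- unclass(v) * t
  mx <- max(sqrt(w[, , , 1]^2 + w[, , , 2]^2 + w[, , , 3]^2))
  if (!is.finite(mx)) stop("exp_svf: non-finite field")
  if (identical(squaring_steps, "auto")) {
    K <- if (mx < 0.5) 0L else as.integer(ceiling(log2(mx / 0.5)))
  } else {
    K <- as.integer(squaring_steps)
    if (K < 0) stop("exp_svf: squaring_steps must be >= 0")
  }
  if (K > 30L) stop("exp_svf: field too large (more than 30 squaring steps needed)")
  w <- w / 2^K
  # second-order flow start: u = w + (Dw) w / 2
  u <- w
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + deriv_axis(w[, , , i], j) * w[, , , j]
    u[, , , i] <- u[, , , i] + 0.5 * acc
  }
  dm <- dim(u)[1:3]
  for (k in seq_len(K)) {
    s <- cpp_sample_displaced(u, dm, 3L, u)
    u <- u + array(s, dim(u))
  }
  deformation_field(u, voxel_spacing(v))
}

#' Compose two deformation fields
#'
#' Returns the deformation `(phi_outer o phi_inner)(x) = phi_outer(phi_inner(x))`.
#' The outer displacement is interpolated trilinearly at the inner-mapped
#' positions; lookups outside the grid are clamped to the boundary.
#'
#' @param phi_outer,phi_inner [deformation_field()]s on the same grid.
#' @return A [deformation_field()].
#' @export
compose <- function(phi_outer, phi_inner) {
  phi_outer <- as_deformation(phi_outer)
  phi_inner <- as_deformation(phi_inner)
  check_same_grid(phi_outer, phi_inner, "deformation fields")
  dm <- grid_shape(phi_inner)
  s <- cpp_sample_displaced(unclass(phi_outer), dm, 3L, unclass(phi_inner))
  deformation_field(unclass(phi_inner) + array(s, dim(phi_inner)),
                    voxel_spacing(phi_inner))
}

#' Warp an image by a deformation
#'
#' Resamples `img` under the pull-back convention `out(x) = img(phi(x))` with
#' trilinear interpolation and clamped boundary lookups. This matches the
#' composition `M o Exp(v)` used by the registration cost.
#'
#' @param img a [scalar_volume()].
#' @param phi a [deformation_field()] on the same grid.
#' @return A [scalar_volume()].
#' @export
warp_image <- function(img, phi) {
  img <- as_volume(img)
  phi <- as_deformation(phi)
  check_same_grid(img, phi, "image and deformation")
  dm <- grid_shape(img)
  s <- cpp_sample_displaced(unclass(img), dm, 1L, unclass(phi))
  scalar_volume(array(s, dm), voxel_spacing(img))
}

#' Gaussian smoothing of a velocity field
#'
#' Componentwise separable Gaussian convolution with standard deviation
#' `sigma` (voxel units), using edge replication at the boundary so that a
#' constant field is preserved exactly. `sigma = 0` returns the input
#' unchanged.
#'
#' @param v a [velocity_field()].
#' @param sigma standard deviation in voxels (>= 0).
#' @return A smoothed [velocity_field()].
#' @export
gaussian_smooth_field <- function(v, sigma) {
  v <- as_velocity(v)
  if (!is.finite(sigma) || sigma < 0) stop("gaussian_smooth_field: sigma must be >= 0")
  if (sigma == 0) return(v)
  out <- unclass(v)
  for (c in 1:3) out[, , , c] <- smooth3(out[, , , c], sigma)
  velocity_field(out, voxel_spacing(v))
}

#' BCH composition of two velocity fields
#'
#' Approximates the SVF of the composed deformation `Exp(v) o Exp(u)` by the
#' Baker-Campbell-Hausdorff series: order 1 gives `v + u`; order 2 adds half
#' the Lie bracket `[v, u] = (Dv)u - (Du)v`, with the Jacobians `Dv`, `Du`
#' computed by central finite differences.
#'
#' @param v,u [velocity_field()]s on the same grid.
#' @param order series order, 1 or 2.
#' @return A [velocity_field()].
#' @export
bch_compose <- function(v, u, order = 2L) {
  v <- as_velocity(v); u <- as_velocity(u)
  check_same_grid(v, u, "velocity fields")
  if (!order %in% c(1L, 2L)) stop("bch_compose: order must be 1 or 2")
  out <- unclass(v) + unclass(u)
  if (order == 2L) out <- out + 0.5 * unclass(lie_bracket(v, u))
  velocity_field(out, voxel_spacing(v))
}

#' Lie bracket of two velocity fields
#'
#' `[v, u] = (Dv)u - (Du)v` by central differences (one-sided at the
#' boundary faces).
#'
#' @param v,u [velocity_field()]s on the same grid.
#' @return A [velocity_field()].
#' @export
lie_bracket <- function(v, u) {
  v <- unclass(as_velocity(v)); u <- unclass(as_velocity(u))
  out <- array(0, dim(v))
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) {
      acc <- acc + deriv_axis(v[, , , i], j) * u[, , , j] -
                   deriv_axis(u[, , , i], j) * v[, , , j]
    }
    out[, , , i] <- acc
  }
  velocity_field(out)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the 3x3 spatial Jacobian of `phi(x) = x + u(x)`, i.e. the
#' local volume ratio of the deformation: values above 1 mark expansion,
#' below 1 contraction.
#'
#' @param phi a [deformation_field()].
#' @return A [scalar_volume()] of determinants.
#' @export
jacobian_determinant <- function(phi) {
  phi <- as_deformation(phi)
  u <- unclass(phi)
  J <- vector("list", 9)
  for (i in 1:3) for (j in 1:3) {
    d <- deriv_axis(u[, , , i], j)
    if (i == j) d <- d + 1
    J[[(i - 1) * 3 + j]] <- d
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  scalar_volume(det, voxel_spacing(phi))
}

#' Divergence of a velocity field
#'
#' `div v = dv1/dx + dv2/dy + dv3/dz` by central differences. Positive values
#' mark local volume inflow (expansion sources), negative values outflow.
#'
#' @param v a [velocity_field()].
#' @return A [scalar_volume()].
#' @export
divergence <- function(v) {
  v <- unclass(as_velocity(v))
  scalar_volume(deriv_axis(v[, , , 1], 1) + deriv_axis(v[, , , 2], 2) +
                deriv_axis(v[, , , 3], 3))
}

#' Geodesic length map of a velocity field
#'
#' Arc length traveled by a particle seeded at each voxel and advected along
#' the (stationary) flow of `v` for unit time, by explicit Euler integration:
#' `x_{k+1} = x_k + dt * v(x_k)` with `dt = 1/steps`, accumulating
#' `|v(x_k)| * dt`.
#'
#' @param v a [velocity_field()].
#' @param integration_steps number of Euler steps (>= 1), default 16.
#' @return A [scalar_volume()] of path lengths (voxel units).
#' @export
geodesic_length <- function(v, integration_steps = 16L) {
  v <- as_velocity(v)
  steps <- as.integer(integration_steps)
  if (steps < 1L) stop("geodesic_length: integration_steps must be >= 1")
  dm <- grid_shape(v)
  pos <- grid_positions(dm)
  dt <- 1 / steps
  gl <- numeric(prod(dm))
  vd <- unclass(v)
  for (k in seq_len(steps)) {
    s <- cpp_sample_trilinear(vd, dm, 3L, pos$x, pos$y, pos$z)
    speed <- sqrt(s[, 1]^2 + s[, 2]^2 + s[, 3]^2)
    gl <- gl + speed * dt
    pos$x <- pos$x + s[, 1] * dt
    pos$y <- pos$y + s[, 2] * dt
    pos$z <- pos$z + s[, 3] * dt
  }
  scalar_volume(array(gl, dm), voxel_spacing(v))
}

#' Squared L2 norm of a velocity field
#'
#' Sum over (optionally masked) voxels of the squared vector magnitude
#' `<v(q), v(q)>`. This is the squared-norm form of the image-manifold
#' distance used for template selection.
#'
#' @param v a [velocity_field()].
#' @param mask optional binary [scalar_volume()] (or 3D 0/1 array).
#' @return A single number.
#' @export
field_squared_norm <- function(v, mask = NULL) {
  v <- as_velocity(v)
  s <- vector_norm3(v)^2
  if (is.null(mask)) return(sum(s))
  if (!identical(dim(unclass(mask))[1:3], grid_shape(v)))
    stop("field_squared_norm: mask shape mismatch")
  check_binary_mask(mask)
  sum(s[unclass(mask) > 0])
}

# ---- internal numerics ------------------------------------------------------

as_volume <- function(x) {
  if (inherits(x, "scalar_volume")) x else scalar_volume(x)
}
as_velocity <- function(x) {
  if (inherits(x, "velocity_field")) x else velocity_field(x)
}
as_deformation <- function(x) {
  if (inherits(x, "deformation_field")) x
  else if (inherits(x, "velocity_field"))
    stop("expected a deformation_field; use exp_svf() to exponentiate an SVF")
  else deformation_field(x)
}

# Partial derivative of a 3D array along one axis: central differences in the
# interior, one-sided at the two boundary faces. Grid step is one voxel.
deriv_axis <- function(a, axis) {
  n <- dim(a)[axis]
  g <- array(0, dim(a))
  ix <- function(i) switch(axis,
    a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  asg <- function(i, val) {
    switch(axis, g[i, , ] <<- val, g[, i, ] <<- val, g[, , i] <<- val)
  }
  if (n >= 3) asg(2:(n - 1), (ix(3:n) - ix(1:(n - 2))) / 2)
  asg(1, ix(2) - ix(1))
  asg(n, ix(n) - ix(n - 1))
  g
}

# 1D Gaussian convolution matrix with edge replication (rows sum to 1).
smooth1d_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in (-r):r) {
    j <- pmin(pmax(idx - t, 1L), n)
    ij <- cbind(idx, j)
    M[ij] <- M[ij] + k[t + r + 1]
  }
  M
}

# Separable Gaussian smoothing of a 3D array (edge replication).
smooth3 <- function(a, sigma) {
  dm <- dim(a)
  # axis 1
  a <- array(smooth1d_matrix(dm[1], sigma) %*% matrix(a, dm[1]), dm)
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  a <- array(smooth1d_matrix(dm[2], sigma) %*% matrix(a, dm[2]), dm[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 1, 2))
  a <- array(smooth1d_matrix(dm[3], sigma) %*% matrix(a, dm[3]), dm[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

# Voxel-center coordinate vectors (1-based) of a grid, column-major order.
grid_positions <- function(shape) {
  list(x = rep(seq_len(shape[1]), times = shape[2] * shape[3]),
       y = rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
       z = rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}

# Trilinear resampling of a 3D array to a new shape (align-corners mapping).
resize3 <- function(a, new_shape) {
  dm <- dim(a)
  coord <- function(n_new, n_old) {
    if (n_new == 1) rep(1, 1)
    else (seq_len(n_new) - 1) * (n_old - 1) / (n_new - 1) + 1
  }
  cx <- coord(new_shape[1], dm[1])
  cy <- coord(new_shape[2], dm[2])
  cz <- coord(new_shape[3], dm[3])
  px <- rep(cx, times = new_shape[2] * new_shape[3])
  py <- rep(rep(cy, each = new_shape[1]), times = new_shape[3])
  pz <- rep(cz, each = new_shape[1] * new_shape[2])
  s <- cpp_sample_trilinear(a, dm, 1L, px, py, pz)
  array(s, new_shape)
}
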