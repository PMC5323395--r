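#' @useDynLib svfmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd var median quantile
NULL

#' Scalar volume
#'
#' A 3D scalar grid (image, mask or statistical map) with per-axis voxel
#' spacing carried as metadata. Spacing is recorded for input/output but the
#' differential operators work in voxel units on the assumption of a
#' near-isotropic grid.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @return An object of class `scalar_volume` (a classed 3D array).
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3(data)
  check_spacing(spacing)
  if (!all(is.finite(data))) stop("scalar_volume: data must be finite")
  structure(data, spacing = as.numeric(spacing),
            class = c("scalar_volume", "array"))
}

#' Stationary velocity field
#'
#' A 3D grid of 3-vectors in voxel units, stored as an `(nx, ny, nz, 3)`
#' array. The vector component order matches the axis order of the grid.
#'
#' @param data 4D numeric array with last dimension 3.
#' @param spacing numeric length-3 voxel size (mm).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array4(data)
  check_spacing(spacing)
  if (!all(is.finite(data))) stop("velocity_field: data must be finite")
  structure(data, spacing = as.numeric(spacing),
            class = c("velocity_field", "array"))
}

#' Deformation field
#'
#' A deformation phi(x) = x + u(x), stored as the displacement u on the voxel
#' grid (an `(nx, ny, nz, 3)` array in voxel units); the identity part is
#' added on demand. For u = 0 the deformation is the identity.
#'
#' @param disp 4D numeric displacement array with last dimension 3.
#' @param spacing numeric length-3 voxel size (mm).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(disp, spacing = c(1, 1, 1)) {
  disp <- as_array4(disp)
  check_spacing(spacing)
  if (!all(is.finite(disp))) stop("deformation_field: displacement must be finite")
  structure(disp, spacing = as.numeric(spacing),
            class = c("deformation_field", "array"))
}

#' Identity deformation on a grid
#'
#' @param shape integer length-3 grid shape.
#' @param spacing voxel size.
#' @return A `deformation_field` with zero displacement.
#' @export
identity_deformation <- function(shape, spacing = c(1, 1, 1)) {
  deformation_field(array(0, c(shape, 3L)), spacing)
}

#' Zero velocity field on a grid
#'
#' @inheritParams identity_deformation
#' @return A `velocity_field` of zeros.
#' @export
zero_velocity <- function(shape, spacing = c(1, 1, 1)) {
  velocity_field(array(0, c(shape, 3L)), spacing)
}

#' Grid shape of a volume or field
#'
#' @param x a `scalar_volume`, `velocity_field` or `deformation_field`.
#' @return Integer length-3 spatial shape.
#' @export
grid_shape <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("not a gridded object")
  d[1:3]
}

#' Voxel spacing of a volume or field
#'
#' @inheritParams grid_shape
#' @return Numeric length-3 spacing (mm); defaults to 1 when absent.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x), collapse = "x"),
              paste(signif(voxel_spacing(x), 3), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field %s, spacing %s mm, max |v| = %.4g voxels>\n",
              paste(dim(x)[1:3], collapse = "x"),
              paste(signif(voxel_spacing(x), 3), collapse = "x"),
              max_vector_norm(x)))
  invisible(x)
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field %s, spacing %s mm, max |u| = %.4g voxels>\n",
              paste(dim(x)[1:3], collapse = "x"),
              paste(signif(voxel_spacing(x), 3), collapse = "x"),
              max_vector_norm(x)))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_array3 <- function(x) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stop("expected a 3D array")
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

as_array4 <- function(x) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != 4 || dim(x)[4] != 3)
    stop("expected an (nx, ny, nz, 3) array")
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  invisible(spacing)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(grid_shape(a), grid_shape(b)))
    stop(sprintf("%s must share grid shape (%s vs %s)", what,
                 paste(grid_shape(a), collapse = "x"),
                 paste(grid_shape(b), collapse = "x")))
  invisible(TRUE)
}

# Per-voxel Euclidean norm of a 4D vector array, returned as a 3D array.
vector_norm3 <- function(v) {
  v <- unclass(v)
  sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
}

max_vector_norm <- function(v) max(vector_norm3(v))

# Logical 3D array marking the interior of a grid (margin voxels removed).
interior_mask <- function(shape, margin = 2L) {
  m <- array(FALSE, shape)
  idx <- lapply(shape, function(n) (margin + 1L):(n - margin))
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

# Binary check for masks; accepts logical or 0/1 numeric.
check_binary_mask <- function(mask) {
  u <- unique(as.vector(unclass(mask)))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1)")
  invisible(TRUE)
}
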