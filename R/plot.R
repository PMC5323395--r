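#' Plot an axial slice of a volume or map
#'
#' Quick-look display of one z-slice of a [scalar_volume()] (image, mask,
#' T-squared / q map). `NA` voxels (outside the analysis mask) are blanked.
#'
#' @param x a [scalar_volume()].
#' @param z slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @return The slice matrix, invisibly.
#' @export
plot_slice <- function(x, z = NULL, ...) {
  a <- unclass(as_volume_na(x))
  if (is.null(z)) z <- ceiling(dim(a)[3] / 2)
  sl <- a[, , z]
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl, asp = 1,
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  col = grDevices::gray.colors(128, 0, 1), ...)
  invisible(sl)
}

as_volume_na <- function(x) {
  if (inherits(x, "scalar_volume")) x else scalar_volume_na(x)
}
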