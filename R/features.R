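# Voxelwise features derived from a normalized SVF, and their assembly into
# per-subject vectors: z-scored per voxel-channel across subjects, decimated
# by a factor of 4 per axis (nearest neighbor), and restricted to the brain
# mask. Channel order is fixed: SVFx, SVFy, SVFz, JD, Div, GL, Defx, Defy,
# Defz.

.feature_channel_order <- c("SVFx", "SVFy", "SVFz", "JD", "Div", "GL",
                            "Defx", "Defy", "Defz")

#' Derive voxelwise feature channels from a normalized SVF
#'
#' The five features of the method, as scalar channels per voxel:
#' * `SVF` — the three components of the velocity field itself;
#' * `JD` — Jacobian determinant of `Exp(v)` (local volume ratio);
#' * `Div` — divergence of `v` (local volume in/outflow);
#' * `GL` — geodesic length of the flow (path length per particle);
#' * `Def` — the three displacement components of `Exp(v)`.
#'
#' The full set yields 9 scalar channels in the fixed order
#' `SVFx, SVFy, SVFz, JD, Div, GL, Defx, Defy, Defz`.
#'
#' @param v_norm a normalized [velocity_field()].
#' @param featureset non-empty subset of
#'   `c("SVF", "JD", "Div", "GL", "Def")`.
#' @return Named list of 3D arrays, one per scalar channel.
#' @export
derive_channels <- function(v_norm,
                            featureset = c("SVF", "JD", "Div", "GL", "Def")) {
  v_norm <- as_velocity(v_norm)
  if (length(featureset) == 0) stop("derive_channels: empty featureset")
  featureset <- match.arg(featureset, several.ok = TRUE)
  out <- list()
  vd <- unclass(v_norm)
  needs_phi <- any(c("JD", "Def") %in% featureset)
  phi <- if (needs_phi) exp_svf(v_norm, 1) else NULL
  if ("SVF" %in% featureset) {
    out$SVFx <- vd[, , , 1]; out$SVFy <- vd[, , , 2]; out$SVFz <- vd[, , , 3]
  }
  if ("JD" %in% featureset) out$JD <- unclass(jacobian_determinant(phi))
  if ("Div" %in% featureset) out$Div <- unclass(divergence(v_norm))
  if ("GL" %in% featureset) out$GL <- unclass(geodesic_length(v_norm))
  if ("Def" %in% featureset) {
    ud <- unclass(phi)
    out$Defx <- ud[, , , 1]; out$Defy <- ud[, , , 2]; out$Defz <- ud[, , , 3]
  }
  out[intersect(.feature_channel_order, names(out))]
}

#' Assemble per-subject feature vectors
#'
#' For each scalar channel: decimate by taking every `downsample`-th voxel per
#' axis (nearest-neighbor downsampling, phase offset 0), decimate the mask
#' identically, flatten the retained in-mask voxels, and concatenate channels.
#' Z-scoring is per voxel-channel across subjects with mean and standard
#' deviation estimated on `train_index` rows only (and applied to all rows),
#' so that no test-subject information enters the normalization;
#' zero-variance voxels get a denominator floored at `1e-8`.
#'
#' @param subject_channels list (one element per subject, in manifest order)
#'   of named channel lists as returned by [derive_channels()].
#' @param mask binary [scalar_volume()] on the full-resolution grid.
#' @param downsample decimation factor per axis (default 4).
#' @param scale `"zscore"` (default) or `"none"` to keep raw values.
#' @param train_index rows used to estimate z-score statistics (default all).
#' @return A `feature_matrix`: an N x D matrix with attributes `stage`
#'   (`"downsampled_h"`), `feature_names` (channel of each column),
#'   `mask_index` (retained voxel linear index in the decimated grid), and,
#'   when z-scored, `center` and `scale`.
#' @export
assemble_matrix <- function(subject_channels, mask, downsample = 4L,
                            scale = c("zscore", "none"),
                            train_index = seq_along(subject_channels)) {
  scale <- match.arg(scale)
  if (length(subject_channels) == 0) stop("assemble_matrix: no subjects")
  check_binary_mask(mask)
  ds <- as.integer(downsample)
  if (ds < 1L) stop("assemble_matrix: downsample must be >= 1")
  ch_names <- names(subject_channels[[1]])
  if (is.null(ch_names) || length(ch_names) == 0)
    stop("assemble_matrix: subjects must carry named channels")

  dm <- dim(unclass(mask))
  sel <- lapply(dm, function(n) seq(1L, n, by = ds))
  mask_ds <- unclass(mask)[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  keep <- which(mask_ds > 0)
  if (length(keep) == 0) stop("assemble_matrix: empty mask after decimation")

  n <- length(subject_channels)
  X <- matrix(0, n, length(keep) * length(ch_names))
  for (i in seq_len(n)) {
    chs <- subject_channels[[i]]
    if (!identical(names(chs), ch_names))
      stop("assemble_matrix: subject ", i, " has mismatched channels")
    row <- unlist(lapply(chs, function(a) {
      a[sel[[1]], sel[[2]], sel[[3]], drop = FALSE][keep]
    }), use.names = FALSE)
    X[i, ] <- row
  }
  if (!all(is.finite(X))) stop("assemble_matrix: non-finite feature values")
  feature_names <- rep(ch_names, each = length(keep))

  center <- NULL; scl <- NULL
  if (scale == "zscore") {
    zs <- zscore_fit(X[train_index, , drop = FALSE])
    X <- zscore_apply(zs, X)
    center <- zs$center; scl <- zs$scale
  }
  structure(X, stage = "downsampled_h", feature_names = feature_names,
            mask_index = keep, center = center, scale = scl,
            class = c("feature_matrix", "matrix"))
}

#' Fit per-column z-score statistics
#'
#' Column means and standard deviations (denominator floored at `1e-8` for
#' zero-variance columns) estimated on training rows.
#'
#' @param X numeric matrix (training rows only).
#' @return List with `center` and `scale` vectors.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, center)^2) * nrow(X) / max(1, nrow(X) - 1))
  list(center = center, scale = pmax(s, 1e-8))
}

#' Apply z-score statistics to a matrix
#'
#' @param stats output of [zscore_fit()].
#' @param X matrix with matching columns.
#' @return The standardized matrix.
#' @export
zscore_apply <- function(stats, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix stage=%s: %d subjects x %d features (%s)>\n",
              attr(x, "stage"), nrow(x), ncol(x),
              paste(unique(attr(x, "feature_names")), collapse = ", ")))
  invisible(x)
}
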