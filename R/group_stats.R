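# Voxelwise group comparison of transported SVFs: per-voxel two-sample
# Hotelling T-squared on the 3-vector observations, F-transformed p-values,
# Benjamini-Yekutieli FDR correction (valid under arbitrary dependence), and
# thresholded significance maps. A Shapiro-Wilk screen reports how well the
# per-voxel normality assumption holds in each group.

#' Voxelwise Shapiro-Wilk normality screen
#'
#' For every in-mask voxel, each of the three SVF components is tested across
#' subjects with a Shapiro-Wilk test at `alpha`; the voxel "fits normal" iff
#' all three components pass. Degenerate (constant) components are counted as
#' passing. Returns the in-mask passing fraction and a pass map.
#'
#' @param svfs list of at least 3 [velocity_field()]s on a shared grid.
#' @param mask binary [scalar_volume()].
#' @param alpha per-test significance level (default 0.05).
#' @return List with `fraction` (in-mask pass fraction), `pass_map` (binary
#'   [scalar_volume()], zero outside the mask) and `n_degenerate` (count of
#'   constant voxel-components encountered).
#' @export
voxelwise_shapiro <- function(svfs, mask, alpha = 0.05) {
  if (length(svfs) < 3) stop("voxelwise_shapiro: at least 3 subjects required")
  check_binary_mask(mask)
  dm <- grid_shape(svfs[[1]])
  idx <- which(unclass(mask) > 0)
  comp <- stack_component_matrix(svfs, idx)   # list of 3 (nsub x nvox)
  pass <- rep(TRUE, length(idx))
  n_deg <- 0L
  for (c in 1:3) {
    M <- comp[[c]]
    for (k in seq_along(idx)) {
      x <- M[, k]
      if (max(x) - min(x) < 1e-12) { n_deg <- n_deg + 1L; next }
      p <- stats::shapiro.test(x)$p.value
      if (p <= alpha) pass[k] <- FALSE
    }
  }
  pm <- array(0, dm)
  pm[idx] <- as.numeric(pass)
  list(fraction = mean(pass), pass_map = scalar_volume(pm),
       n_degenerate = n_deg)
}

#' Voxelwise two-sample Hotelling T-squared map
#'
#' At each in-mask voxel the two groups' SVF vectors form an `n1 x 3` and an
#' `n2 x 3` sample. The statistic is
#' `T2 = (n1 n2 / (n1 + n2)) * t(d) %*% solve(Sp) %*% d` with `d` the mean
#' difference and `Sp` the pooled covariance; p-values come from
#' `F = ((n1 + n2 - p - 1) / ((n1 + n2 - 2) p)) * T2 ~ F(p, n1 + n2 - p - 1)`
#' with `p = 3`. Near-singular pooled covariances are stabilized by adding a
#' ridge of `1e-8 * tr(Sp) / 3` to the diagonal; affected voxels are counted.
#'
#' @param group1,group2 lists of [velocity_field()]s (shared grid).
#' @param mask binary [scalar_volume()].
#' @return An object of class `stat_map`: list with `t2`, `p` (both
#'   [scalar_volume()]s, `NA` outside the mask), `q` (`NULL` until
#'   [stat_map_fdr()]), `mask`, group sizes `n1`, `n2`, and `n_ridged`.
#' @export
hotelling_t2_map <- function(group1, group2, mask) {
  n1 <- length(group1); n2 <- length(group2)
  p <- 3
  if (n1 < 2 || n2 < 2 || n1 + n2 - p - 1 < 1)
    stop("hotelling_t2_map: group sizes too small for the F reference ",
         "distribution (need n1, n2 >= 2 and n1 + n2 >= 5)")
  check_binary_mask(mask)
  dm <- grid_shape(group1[[1]])
  idx <- which(unclass(mask) > 0)
  A <- stack_component_matrix(group1, idx)
  B <- stack_component_matrix(group2, idx)

  m1 <- lapply(A, colMeans); m2 <- lapply(B, colMeans)
  ctr <- function(M, m) M - matrix(m, nrow(M), length(m), byrow = TRUE)
  Ac <- Map(ctr, A, m1); Bc <- Map(ctr, B, m2)
  # pooled covariance entries (vectorized over voxels)
  S <- matrix(0, 6, length(idx))  # s11 s22 s33 s12 s13 s23
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:6) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    S[k, ] <- (colSums(Ac[[a]] * Ac[[b]]) + colSums(Bc[[a]] * Bc[[b]])) /
              (n1 + n2 - 2)
  }
  d1 <- m1[[1]] - m2[[1]]; d2 <- m1[[2]] - m2[[2]]; d3 <- m1[[3]] - m2[[3]]

  t2q <- function(S) {
    s11 <- S[1, ]; s22 <- S[2, ]; s33 <- S[3, ]
    s12 <- S[4, ]; s13 <- S[5, ]; s23 <- S[6, ]
    det <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
           s13 * (s12 * s23 - s22 * s13)
    # adjugate solve of S x = d
    i11 <- s22 * s33 - s23^2; i12 <- s13 * s23 - s12 * s33
    i13 <- s12 * s23 - s13 * s22
    i22 <- s11 * s33 - s13^2; i23 <- s12 * s13 - s11 * s23
    i33 <- s11 * s22 - s12^2
    quad <- d1 * (i11 * d1 + i12 * d2 + i13 * d3) +
            d2 * (i12 * d1 + i22 * d2 + i23 * d3) +
            d3 * (i13 * d1 + i23 * d2 + i33 * d3)
    list(quad = quad, det = det)
  }
  r <- t2q(S)
  tr3 <- (S[1, ] + S[2, ] + S[3, ]) / 3
  singular <- !is.finite(r$det) | r$det <= 1e-12 * pmax(tr3, 1e-30)^3
  n_ridged <- sum(singular)
  if (n_ridged > 0) {
    ridge <- 1e-8 * pmax(tr3[singular] * 3, 1e-30) / 3
    Ss <- S[, singular, drop = FALSE]
    Ss[1, ] <- Ss[1, ] + ridge; Ss[2, ] <- Ss[2, ] + ridge
    Ss[3, ] <- Ss[3, ] + ridge
    d1s <- d1; d2s <- d2; d3s <- d3  # closures read d1..d3; subset below
    d1 <- d1[singular]; d2 <- d2[singular]; d3 <- d3[singular]
    rs <- t2q(Ss)
    d1 <- d1s; d2 <- d2s; d3 <- d3s
    r$quad[singular] <- rs$quad
    r$det[singular] <- rs$det + 0  # recomputed with ridge
    r$det[singular][rs$det <= 0] <- NA  # truly degenerate: no information
  }
  t2 <- (n1 * n2 / (n1 + n2)) * r$quad / r$det
  t2[!is.finite(t2) | t2 < 0] <- 0   # degenerate voxels carry no evidence
  fstat <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  pval <- stats::pf(fstat, p, n1 + n2 - p - 1, lower.tail = FALSE)

  t2_map <- array(NA_real_, dm); p_map <- array(NA_real_, dm)
  t2_map[idx] <- t2; p_map[idx] <- pval
  structure(list(t2 = scalar_volume_na(t2_map), p = scalar_volume_na(p_map),
                 q = NULL, mask = as_volume(mask), n1 = n1, n2 = n2,
                 n_ridged = n_ridged),
            class = "stat_map")
}

#' FDR correction of p-values
#'
#' Benjamini-Yekutieli (default; valid under arbitrary dependence) or
#' Benjamini-Hochberg step-up adjustment via [stats::p.adjust()].
#'
#' @param p numeric p-values in `[0, 1]` (NAs passed through).
#' @param method `"BY"` (default) or `"BH"`.
#' @return Adjusted q-values in input order.
#' @export
fdr_correct <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  pv <- p[!is.na(p)]
  if (any(pv < 0 | pv > 1)) stop("fdr_correct: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Attach FDR-corrected q-values to a stat map
#'
#' @param stat a [hotelling_t2_map()] result.
#' @param method passed to [fdr_correct()].
#' @return The `stat_map` with its `q` volume filled in.
#' @export
stat_map_fdr <- function(stat, method = "BY") {
  stopifnot(inherits(stat, "stat_map"))
  q <- unclass(stat$p)
  q[] <- fdr_correct(as.vector(unclass(stat$p)), method)
  stat$q <- scalar_volume_na(q)
  stat
}

#' Threshold a stat map at an FDR level
#'
#' Binary map of voxels with corrected `q <= q_threshold` (computed with BY
#' first if absent); zero outside the analysis mask.
#'
#' @param stat a `stat_map`.
#' @param q_threshold significance threshold on the corrected q-values
#'   (default 0.001).
#' @return A binary [scalar_volume()].
#' @export
threshold_map <- function(stat, q_threshold = 0.001) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$q)) stat <- stat_map_fdr(stat)
  q <- unclass(stat$q)
  out <- array(0, dim(q))
  out[!is.na(q) & q <= q_threshold] <- 1
  scalar_volume(out)
}

#' @export
print.stat_map <- function(x, ...) {
  nsig <- if (!is.null(x$q)) sum(unclass(x$q) <= 0.001, na.rm = TRUE) else NA
  cat(sprintf("<stat_map n1=%d n2=%d, max T2=%.3g, ridged=%d voxels%s>\n",
              x$n1, x$n2, max(unclass(x$t2), na.rm = TRUE), x$n_ridged,
              if (!is.na(nsig)) sprintf(", q<=0.001 at %d voxels", nsig) else ""))
  invisible(x)
}

# stack the three components of a list of fields at masked voxels:
# returns list of three (nsubjects x nvoxel) matrices.
stack_component_matrix <- function(svfs, idx) {
  dm <- grid_shape(svfs[[1]])
  nvox <- prod(dm)
  lapply(1:3, function(c) {
    t(vapply(svfs, function(v) {
      vd <- unclass(as_velocity(v))
      vd[idx + (c - 1) * nvox]
    }, numeric(length(idx))))
  })
}

# scalar_volume that tolerates NAs (stat maps are NA outside the mask)
scalar_volume_na <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3(data)
  check_spacing(spacing)
  structure(data, spacing = as.numeric(spacing),
            class = c("scalar_volume", "array"))
}
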