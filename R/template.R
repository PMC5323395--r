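# Data-driven template selection. The pairwise "geodesic distance" between two
# images is the squared L2 norm of the SVF that registers one to the other;
# classical multidimensional scaling embeds the cohort in the plane and the
# image closest to the embedding centroid is the least-biased template.

#' Pairwise geodesic distance matrix of a set of images
#'
#' For every ordered pair `(i, j)` the SVF registering image `i` (moving) to
#' image `j` (fixed) is computed and its squared L2 norm taken as the
#' distance. The matrix is then symmetrized as `(d + t(d)) / 2` (registration
#' is not perfectly symmetric) and the diagonal forced to zero.
#'
#' @param images list of at least 3 [scalar_volume()]s on a shared grid.
#' @param cfg a [registration_config()].
#' @param ids optional character labels; defaults to `img1, img2, ...`.
#' @return An object of class `distance_matrix`: the symmetric N x N matrix
#'   with `subject_ids` as dimnames.
#' @export
pairwise_distances <- function(images, cfg = registration_config(), ids = NULL) {
  n <- length(images)
  if (n < 3) stop("pairwise_distances: at least 3 images required")
  if (is.null(ids)) ids <- paste0("img", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    svf <- logdemons_register(images[[j]], images[[i]], cfg)$svf
    d[i, j] <- field_squared_norm(svf)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a matrix of squared distances into `dim` Euclidean dimensions by
#' double-centering (`B = -0.5 J D J`) and eigendecomposition. The input is
#' treated as already-squared distances — the image-manifold distance used
#' here is defined as a squared norm — so no additional squaring is applied.
#' Negative eigenvalues (non-Euclidean input) are clipped to zero with a
#' warning.
#'
#' @param D square symmetric matrix of squared distances (zero diagonal).
#' @param dim embedding dimension, default 2.
#' @return N x dim matrix of embedding coordinates (columns ordered by
#'   decreasing eigenvalue).
#' @export
classical_mds <- function(D, dim = 2L) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("classical_mds: D must be square")
  n <- nrow(D)
  dim <- min(as.integer(dim), n)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values[seq_len(dim)]
  if (any(lam < -1e-8 * max(abs(e$values), 1)))
    warning("classical_mds: negative eigenvalues clipped to zero (non-Euclidean input)")
  lam <- pmax(lam, 0)
  X <- e$vectors[, seq_len(dim), drop = FALSE] %*% diag(sqrt(lam), dim)
  rownames(X) <- rownames(D)
  X
}

#' Select the least-biased template from an embedding
#'
#' Returns the index of the point nearest (Euclidean) to the arithmetic mean
#' of the embedding; ties are broken by the lowest index.
#'
#' @param embedding N x k matrix of embedding coordinates.
#' @return Integer index of the selected image.
#' @export
select_template <- function(embedding) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 1) stop("select_template: empty embedding")
  ctr <- colMeans(embedding)
  d2 <- rowSums(sweep(embedding, 2, ctr)^2)
  unname(which.min(d2))  # which.min breaks ties by lowest index
}

#' Template selection from baseline images
#'
#' Convenience wrapper chaining [pairwise_distances()], [classical_mds()] and
#' [select_template()].
#'
#' @inheritParams pairwise_distances
#' @return List with `index`, `distances` and `embedding`.
#' @export
choose_template <- function(images, cfg = registration_config(), ids = NULL) {
  d <- pairwise_distances(images, cfg, ids)
  emb <- classical_mds(d, 2L)
  list(index = select_template(emb), distances = d, embedding = emb)
}
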