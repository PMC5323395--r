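# Subject classification: kernel PCA dimensionality reduction (linear or
# Gaussian kernel) followed by a linear soft-margin SVM, evaluated by
# stratified 10-fold cross-validation with a nested grid search over the
# regularization trade-off. Converters ("MCIc") are the positive class.

#' Kernel matrix between two feature matrices
#'
#' Linear: `K = Ha %*% t(Hb)`. Gaussian:
#' `K[i, j] = exp(-||ha_i - hb_j||^2 / (2 theta^2))` with `theta` the kernel
#' standard deviation.
#'
#' @param H_a,H_b numeric matrices with matching feature dimension.
#' @param kind `"linear"` or `"gaussian"`.
#' @param theta Gaussian standard deviation (> 0); ignored for linear.
#' @return `nrow(H_a)` x `nrow(H_b)` kernel matrix.
#' @export
kernel_matrix <- function(H_a, H_b, kind = c("linear", "gaussian"), theta = 1) {
  kind <- match.arg(kind)
  H_a <- as.matrix(H_a); H_b <- as.matrix(H_b)
  if (ncol(H_a) != ncol(H_b)) stop("kernel_matrix: feature dimension mismatch")
  if (kind == "linear") return(H_a %*% t(H_b))
  if (theta <= 0) stop("kernel_matrix: theta must be > 0 for the Gaussian kernel")
  d2 <- outer(rowSums(H_a^2), rowSums(H_b^2), "+") - 2 * H_a %*% t(H_b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * theta^2))
}

#' Fit kernel PCA
#'
#' Double-centers the training kernel, eigendecomposes it, and retains the
#' top components with eigenvalue above `1e-10` (at most `N - 1`). Scores are
#' scaled so that projections are principal-component coordinates: for the
#' linear kernel they equal direct PCA scores of the (column-centered)
#' training matrix up to per-component sign.
#'
#' @param H_train N x D feature matrix (N >= 2).
#' @param kind,theta kernel choice, see [kernel_matrix()]. For the Gaussian
#'   kernel, `theta = "median"` resolves the kernel width to the median
#'   pairwise Euclidean distance among training rows (the median heuristic);
#'   with high-dimensional z-scored features a fixed `theta = 1` drives the
#'   kernel toward the identity matrix, leaving no usable geometry.
#' @param n_components `"auto"` (all retained) or an integer cap.
#' @return An object of class `kpca_model`.
#' @export
kpca_fit <- function(H_train, kind = c("linear", "gaussian"), theta = 1,
                     n_components = "auto") {
  kind <- match.arg(kind)
  H_train <- as.matrix(H_train)
  n <- nrow(H_train)
  if (n < 2) stop("kpca_fit: at least 2 training rows required")
  if (kind == "gaussian" && identical(theta, "median")) {
    dd <- stats::dist(H_train)
    theta <- stats::median(dd)
    if (!is.finite(theta) || theta <= 0) theta <- 1
  }
  K <- kernel_matrix(H_train, H_train, kind, theta)
  rm_ <- rowMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  keep <- which(e$values > 1e-10)
  keep <- keep[keep <= n - 1L]
  if (!identical(n_components, "auto"))
    keep <- keep[seq_len(min(length(keep), as.integer(n_components)))]
  if (length(keep) == 0) stop("kpca_fit: kernel has rank 0 after centering")
  structure(list(kind = kind, theta = theta, H_train = H_train,
                 row_means = rm_, grand_mean = gm,
                 eigvals = e$values[keep],
                 eigvecs = e$vectors[, keep, drop = FALSE],
                 n_components = length(keep)),
            class = "kpca_model")
}

#' Project feature vectors with a fitted kernel PCA
#'
#' Computes test kernel rows against the training vectors, centers them with
#' the training statistics, and projects onto the retained components.
#' Projecting the training set itself reproduces the training scores.
#'
#' @param model a [kpca_fit()] result.
#' @param H matrix of feature vectors (matching dimension).
#' @return m x d matrix of reduced coordinates (stage `reduced_f`).
#' @export
kpca_project <- function(model, H) {
  stopifnot(inherits(model, "kpca_model"))
  H <- as.matrix(H)
  if (ncol(H) != ncol(model$H_train)) stop("kpca_project: dimension mismatch")
  Kt <- kernel_matrix(H, model$H_train, model$kind, model$theta)
  n <- nrow(model$H_train)
  Ktc <- Kt - outer(rowMeans(Kt), rep(1, n)) -
         outer(rep(1, nrow(H)), model$row_means) + model$grand_mean
  Ktc %*% model$eigvecs %*% diag(1 / sqrt(model$eigvals), model$n_components)
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model %s kernel%s: %d components from %d subjects>\n",
              x$kind, if (x$kind == "gaussian") sprintf(" (theta=%g)", x$theta) else "",
              x$n_components, nrow(x$H_train)))
  invisible(x)
}

#' Train a linear soft-margin SVM
#'
#' Minimizes `||w||^2 + c * sum_i max(0, 1 - y_i (<w, f_i> + b))` over `w`
#' and an unpenalized bias `b`, by SMO on the dual (maximal-violating-pair
#' working-set selection) to a tight KKT tolerance. The decision value of a
#' sample is `<w, f> + b`; the predicted label its sign.
#'
#' @param F_train m x d matrix of (reduced) feature vectors.
#' @param y labels in `{-1, +1}` (both classes present).
#' @param c regularization trade-off of the hinge term (> 0).
#' @param tol KKT violation tolerance of the dual solver.
#' @param max_iter iteration cap.
#' @return An object of class `svm_model`: list with `w`, `b`, `c`,
#'   `objective` (the primal objective above) and `alpha`.
#' @export
svm_train <- function(F_train, y, c = 1, tol = 1e-8, max_iter = 200000L) {
  X <- as.matrix(F_train)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("svm_train: labels must be -1/+1")
  if (length(unique(y)) < 2) stop("svm_train: both classes must be present")
  if (c <= 0) stop("svm_train: c must be > 0")
  n <- nrow(X)
  C <- c / 2  # ||w||^2 + c*hinge == 2 * (0.5 ||w||^2 + (c/2)*hinge)

  Q <- tcrossprod(X) * outer(y, y)
  sol <- cpp_smo_solve(Q, y, C, tol, as.integer(max_iter))
  alpha <- sol$alpha
  w <- drop(crossprod(X, alpha * y))
  free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
  b <- if (any(free)) {
    mean(y[free] - X[free, , drop = FALSE] %*% w)
  } else {
    G <- drop(Q %*% alpha) - 1
    yg <- -y * G
    up <- (y > 0 & alpha < C - 1e-15) | (y < 0 & alpha > 1e-15)
    lo <- (y < 0 & alpha < C - 1e-15) | (y > 0 & alpha > 1e-15)
    m_up <- if (any(up)) max(yg[up]) else 0
    m_lo <- if (any(lo)) min(yg[lo]) else 0
    (m_up + m_lo) / 2
  }
  margins <- 1 - y * (X %*% w + b)
  obj <- sum(w^2) + c * sum(pmax(0, margins))
  structure(list(w = w, b = b, c = c, alpha = alpha, objective = obj),
            class = "svm_model")
}

#' Decision values of a linear SVM
#'
#' @param model an [svm_train()] result.
#' @param F_new matrix of feature vectors.
#' @return Numeric decision values `<w, f> + b`.
#' @export
svm_decision <- function(model, F_new) {
  drop(as.matrix(F_new) %*% model$w + model$b)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model d=%d, c=%g, objective=%.6g>\n",
              length(x$w), x$c, x$objective))
  invisible(x)
}

#' Area under the ROC curve by midranks
#'
#' Mann-Whitney statistic on decision values; ties handled by midranks, so an
#' all-tied vector yields 0.5.
#'
#' @param scores numeric decision values.
#' @param labels +1/-1 (or logical) with +1/`TRUE` the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("auc_midrank: both classes required")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

.default_c_grid <- c(1e-3, 1e-2, 1e-1, 0.5, 1, 2, 5, 10, 50, 1e2, 1e3)

#' Cross-validated KPCA + linear SVM classification
#'
#' Stratified k-fold cross-validation of the full recipe. Per outer fold,
#' everything fold-dependent is fit on the training part only: z-score
#' statistics, the KPCA basis, and the SVM regularization trade-off `c`
#' (chosen by an inner stratified 5-fold grid search maximizing accuracy,
#' ties going to the smaller `c`). Held-out decision values are pooled into a
#' single confusion matrix (threshold 0) and ROC.
#'
#' @param H N x D feature matrix, raw (not z-scored); rows in manifest order.
#' @param y labels: `"MCIc"`/`"MCIs"` (or a factor, or +1/-1 numeric).
#' @param kind,theta KPCA kernel, see [kpca_fit()] (`theta = "median"` is
#'   resolved per training fold).
#' @param folds number of outer folds (default 10).
#' @param c_grid candidate values of the SVM trade-off.
#' @param seed integer seed for the fold shuffle.
#' @param positive label of the positive class (default `"MCIc"`).
#' @param inner_folds folds of the nested grid search (default 5; reduced
#'   automatically if a class is too small).
#' @param n_components passed to [kpca_fit()].
#' @return An object of class `cv_report`: list with pooled `metrics`
#'   (ACC, SEN, SPE, F1, AUC), `confusion`, `per_fold` data frame (chosen `c`
#'   and fold metrics), `roc` data frame, pooled `decision_values`, `y`,
#'   `folds` assignment and `seed`.
#' @export
cross_validate <- function(H, y, kind = c("linear", "gaussian"), theta = 1,
                           folds = 10L, c_grid = .default_c_grid, seed = 1L,
                           positive = "MCIc", inner_folds = 5L,
                           n_components = "auto") {
  kind <- match.arg(kind)
  H <- as.matrix(H)
  yb <- to_binary_labels(y, positive)
  n <- length(yb)
  if (n != nrow(H)) stop("cross_validate: labels do not match rows")
  if (n < folds) stop("cross_validate: fewer subjects than folds")
  if (min(sum(yb == 1), sum(yb == -1)) < folds)
    stop("cross_validate: both classes need at least `folds` members for ",
         "stratification; lower `folds`")

  fold_id <- stratified_folds(yb, folds, seed)
  dec <- numeric(n)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    zs <- zscore_fit(H[train, , drop = FALSE])
    Ht <- zscore_apply(zs, H[train, , drop = FALSE])
    Hs <- zscore_apply(zs, H[test, , drop = FALSE])
    c_best <- select_c_inner(H[train, , drop = FALSE], yb[train], kind, theta,
                             c_grid, inner_folds, seed + f, n_components)
    kp <- kpca_fit(Ht, kind, theta, n_components)
    sv <- svm_train(kpca_project(kp, Ht), yb[train], c_best)
    dec[test] <- svm_decision(sv, kpca_project(kp, Hs))
    cm_f <- confusion_counts(dec[test], yb[test])
    per_fold[[f]] <- data.frame(fold = f, c = c_best, n_test = length(test),
                                acc = (cm_f["tp"] + cm_f["tn"]) / length(test))
  }
  cm <- confusion_counts(dec, yb)
  metrics <- c(ACC = unname((cm["tp"] + cm["tn"]) / n),
               SEN = unname(cm["tp"] / (cm["tp"] + cm["fn"])),
               SPE = unname(cm["tn"] / (cm["tn"] + cm["fp"])),
               F1 = unname(2 * cm["tp"] / (2 * cm["tp"] + cm["fp"] + cm["fn"])),
               AUC = auc_midrank(dec, yb))
  structure(list(metrics = metrics, confusion = cm,
                 per_fold = do.call(rbind, per_fold),
                 roc = roc_points(dec, yb), decision_values = dec, y = yb,
                 folds = fold_id, seed = seed, kind = kind, theta = theta),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s kernel: ACC=%.3f SEN=%.3f SPE=%.3f F1=%.3f AUC=%.3f>\n",
              x$kind, x$metrics["ACC"], x$metrics["SEN"], x$metrics["SPE"],
              x$metrics["F1"], x$metrics["AUC"]))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

to_binary_labels <- function(y, positive = "MCIc") {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    return(y)
  }
  y <- as.character(y)
  ifelse(y == positive, 1, -1)
}

stratified_folds <- function(yb, folds, seed) {
  fold_id <- integer(length(yb))
  with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(yb == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

confusion_counts <- function(dec, yb) {
  pred <- ifelse(dec >= 0, 1, -1)
  c(tp = sum(pred == 1 & yb == 1), tn = sum(pred == -1 & yb == -1),
    fp = sum(pred == 1 & yb == -1), fn = sum(pred == -1 & yb == 1))
}

roc_points <- function(dec, yb) {
  ord <- order(dec, decreasing = TRUE)
  tp <- cumsum(yb[ord] == 1); fp <- cumsum(yb[ord] == -1)
  data.frame(threshold = dec[ord],
             tpr = tp / sum(yb == 1), fpr = fp / sum(yb == -1))
}

# Nested grid search: inner stratified CV on the training part only.
select_c_inner <- function(H_train, yb_train, kind, theta, c_grid,
                           inner_folds, seed, n_components) {
  k <- min(inner_folds, sum(yb_train == 1), sum(yb_train == -1))
  if (k < 2 || length(c_grid) == 1) return(c_grid[1])
  fold_id <- stratified_folds(yb_train, k, seed)
  acc <- numeric(length(c_grid))
  for (f in seq_len(k)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    if (length(unique(yb_train[tr])) < 2) next
    zs <- zscore_fit(H_train[tr, , drop = FALSE])
    Ht <- zscore_apply(zs, H_train[tr, , drop = FALSE])
    Hs <- zscore_apply(zs, H_train[te, , drop = FALSE])
    kp <- kpca_fit(Ht, kind, theta, n_components)
    Ft <- kpca_project(kp, Ht); Fs <- kpca_project(kp, Hs)
    for (ci in seq_along(c_grid)) {
      sv <- svm_train(Ft, yb_train[tr], c_grid[ci])
      pred <- ifelse(svm_decision(sv, Fs) >= 0, 1, -1)
      acc[ci] <- acc[ci] + sum(pred == yb_train[te])
    }
  }
  c_grid[which.max(acc)]  # ties -> smallest c (grid is increasing)
}
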