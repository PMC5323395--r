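# KPCA, the linear SVM, and the cross-validation protocol.

test_that("kernel_matrix matches brute-force evaluation", {
  set.seed(1)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(12), 4, 3)
  K <- kernel_matrix(A, B, "linear")
  Kg <- kernel_matrix(A, B, "gaussian", theta = 0.8)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(K[i, j], sum(A[i, ] * B[j, ]), tolerance = 1e-10)
    expect_equal(Kg[i, j], exp(-sum((A[i, ] - B[j, ])^2) / (2 * 0.8^2)),
                 tolerance = 1e-10)
  }
  expect_equal(diag(kernel_matrix(A, A, "gaussian", theta = 2)), rep(1, 5))
  U <- diag(3)
  expect_equal(kernel_matrix(U, U, "linear"), diag(3))
  expect_error(kernel_matrix(A, B, "gaussian", theta = 0), "theta")
  expect_error(kernel_matrix(A, matrix(0, 2, 2), "linear"), "dimension")
})

test_that("linear KPCA equals direct PCA up to component signs", {
  set.seed(7)
  H <- matrix(rnorm(20 * 50), 20, 50)
  kp <- kpca_fit(H, "linear")
  expect_equal(kp$n_components, 19L)
  sc <- kpca_project(kp, H)
  pc <- prcomp(H, center = TRUE, scale. = FALSE)
  for (k in seq_len(kp$n_components)) {
    expect_lt(min(max(abs(sc[, k] - pc$x[, k])),
                  max(abs(sc[, k] + pc$x[, k]))), 1e-8)
  }
  # out-of-sample projection matches the direct-PCA transform oracle
  Hnew <- matrix(rnorm(5 * 50), 5, 50)
  sc2 <- kpca_project(kp, Hnew)
  pc2 <- predict(pc, Hnew)
  for (k in seq_len(kp$n_components)) {
    expect_lt(min(max(abs(sc2[, k] - pc2[, k])),
                  max(abs(sc2[, k] + pc2[, k]))), 1e-6)
  }
})

test_that("KPCA projections are self-consistent and duplicate-stable", {
  set.seed(9)
  H <- matrix(rnorm(12 * 6), 12, 6)
  H[2, ] <- H[1, ]                       # duplicated subject
  kp <- kpca_fit(H, "gaussian", theta = 3)
  sc <- kpca_project(kp, H)
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-8)
  # a test row equal to a training row receives that row's score
  sc_test <- kpca_project(kp, H[5, , drop = FALSE])
  expect_equal(as.vector(sc_test), as.vector(sc[5, ]), tolerance = 1e-8)
  expect_error(kpca_project(kp, matrix(0, 2, 5)), "dimension")
  expect_error(kpca_fit(matrix(1, 4, 3), "linear"), "rank 0")
})

test_that("svm_train solves the hinge-loss objective", {
  set.seed(11)
  X <- rbind(matrix(rnorm(10 * 2), 10, 2) + 2, matrix(rnorm(10 * 2), 10, 2) - 2)
  y <- c(rep(1, 10), rep(-1, 10))
  sv <- svm_train(X, y, c = 1)
  expect_equal(unname(mean(sign(svm_decision(sv, X)) == y)), 1)

  # projected-subgradient reference on the 20-point fixture: the SMO objective
  # must not exceed the reference by more than the contract tolerance
  obj <- function(w, b) sum(w^2) + sum(pmax(0, 1 - y * (X %*% w + b)))
  wb <- c(0, 0, 0); best <- Inf
  for (k in 1:60000) {
    w <- wb[1:2]; b <- wb[3]
    act <- as.vector(1 - y * (X %*% w + b)) > 0
    g <- c(2 * w, 0)
    if (any(act)) {
      g[1:2] <- g[1:2] - colSums(y[act] * X[act, , drop = FALSE])
      g[3] <- -sum(y[act])
    }
    wb <- wb - (0.5 / sqrt(k)) * g
    best <- min(best, obj(wb[1:2], wb[3]))
  }
  expect_lt(sv$objective, best + 1e-4)

  # independent cross-check against the installed libsvm solver
  if (requireNamespace("e1071", quietly = TRUE)) {
    em <- e1071::svm(X, factor(y), kernel = "linear", cost = 0.5,
                     scale = FALSE, tolerance = 1e-8)
    w_e <- drop(t(em$coefs) %*% em$SV); b_e <- -em$rho
    if (em$labels[1] == -1) { w_e <- -w_e; b_e <- -b_e }
    expect_equal(sv$objective, obj(w_e, b_e), tolerance = 1e-6)
  }

  # duplicating every point with c halved leaves the solution unchanged
  sv2 <- svm_train(rbind(X, X), c(y, y), c = 0.5)
  expect_equal(sv2$w, sv$w, tolerance = 1e-6)
  expect_equal(sv2$b, sv$b, tolerance = 1e-6)

  expect_error(svm_train(X, rep(1, 20), c = 1), "both classes")
  expect_error(svm_train(X, y, c = 0), "c must be")
})

test_that("cross-validation is perfect on separable data and null on permuted labels", {
  coh <- separable_cohort()
  cv <- cross_validate(coh$H, coh$y, "linear", folds = 10, seed = 5)
  expect_equal(unname(cv$metrics["ACC"]), 1)
  expect_equal(unname(cv$metrics["AUC"]), 1)
  cvg <- cross_validate(coh$H, coh$y, "gaussian", theta = "median",
                        folds = 10, seed = 5)
  expect_equal(unname(cvg$metrics["ACC"]), 1)

  set.seed(13)
  yp <- sample(coh$y)
  cvp <- cross_validate(coh$H, yp, "linear", folds = 10, seed = 5)
  expect_gte(unname(cvp$metrics["AUC"]), 0.3)
  expect_lte(unname(cvp$metrics["AUC"]), 0.7)
})

test_that("AUC uses midranks and matches the confusion-matrix identities", {
  expect_equal(auc_midrank(rep(0, 10), c(rep(1, 5), rep(-1, 5))), 0.5)
  # invariance under strictly monotone transforms
  set.seed(19)
  s <- rnorm(30); lab <- rep(c(1, -1), 15)
  expect_equal(auc_midrank(s, lab), auc_midrank(exp(s), lab))
  expect_equal(auc_midrank(s, lab), auc_midrank(rank(s), lab))

  coh <- separable_cohort(n_per = 15)
  cv <- cross_validate(coh$H, coh$y, "linear", folds = 5, seed = 2)
  cm <- cv$confusion
  expect_equal(sum(cm), 30)
  expect_equal(unname(cv$metrics["SEN"]),
               unname(cm["tp"] / (cm["tp"] + cm["fn"])))
  expect_equal(unname(cv$metrics["SPE"]),
               unname(cm["tn"] / (cm["tn"] + cm["fp"])))
})

test_that("no test-fold information leaks into the trained models", {
  # re-deriving each fold's model from the training rows alone must reproduce
  # the held-out decision values exactly: the fold pipeline (z-score stats,
  # KPCA basis, inner c selection, SVM) never saw its test rows
  coh <- separable_cohort(n_per = 15)
  cv <- cross_validate(coh$H, coh$y, "linear", folds = 5, seed = 9)
  yb <- ifelse(coh$y == "MCIc", 1, -1)
  for (f in c(1, 3)) {
    train <- which(cv$folds != f); test <- which(cv$folds == f)
    zs <- zscore_fit(coh$H[train, , drop = FALSE])
    Ht <- zscore_apply(zs, coh$H[train, , drop = FALSE])
    Hs <- zscore_apply(zs, coh$H[test, , drop = FALSE])
    c_best <- svfmorph:::select_c_inner(coh$H[train, , drop = FALSE],
                                        yb[train], "linear", 1,
                                        svfmorph:::.default_c_grid, 5L,
                                        9 + f, "auto")
    kp <- kpca_fit(Ht, "linear")
    sv <- svm_train(kpca_project(kp, Ht), yb[train], c_best)
    expect_equal(svm_decision(sv, kpca_project(kp, Hs)),
                 cv$decision_values[test], tolerance = 1e-10)
  }
})

test_that("degenerate fold requests are rejected with guidance", {
  coh <- separable_cohort(n_per = 8)   # 16 subjects, 8 per class
  expect_error(cross_validate(coh$H, coh$y, "linear", folds = 10, seed = 1),
               "lower")
  expect_error(cross_validate(coh$H[1:6, ], coh$y[1:6], "linear",
                              folds = 10, seed = 1), "fewer subjects")
})
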