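#' @include AllGenerics.R
NULL

#' Principal component analysis of a spectrum set
#'
#' Column-mean-centred singular value decomposition of the intensity matrix
#' (spectra in rows). The sign of each loading is fixed so that its
#' largest-magnitude element is positive, making the decomposition
#' reproducible across platforms. The first five components typically carry
#' the variance that separates cell states, so `n_components` defaults to 5.
#'
#' @param object a numeric matrix (spectra in rows) or a [RamanSet-class].
#' @param n_components number of components, at most `min(n - 1, n_points)`.
#' @param ... unused.
#' @return a [PCAModel-class].
#' @export
setMethod("fitPCA", "matrix", function(object, n_components = 5L, ...) {
  X <- object
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  if (n_components > min(n - 1L, p))
    stop("n_components must not exceed min(n - 1, n_points)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  k <- n_components
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  evr <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
  new("PCAModel", center = mu, loadings = V, evr = evr, scores = scores,
      sdev = sv$d[seq_len(k)] / sqrt(max(n - 1L, 1L)), total_variance = total)
})

#' @rdname fitPCA-matrix-method
#' @export
setMethod("fitPCA", "RamanSet", function(object, n_components = 5L, ...)
  fitPCA(intensityMatrix(object), n_components = n_components))

#' Project spectra onto a fitted PCA model
#'
#' @param model a [PCAModel-class].
#' @param newdata numeric matrix (spectra in rows) or a [RamanSet-class].
#' @return score matrix (spectra x components).
#' @export
projectPCA <- function(model, newdata) {
  if (is(newdata, "RamanSet")) newdata <- intensityMatrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L)
  sweep(newdata, 2L, model@center) %*% model@loadings
}

#' Fold-honest k-fold PCA + linear SVM classification
#'
#' Stratified k-fold cross-validation in which the PCA is fitted on the
#' training rows of each fold only, both partitions are projected through
#' that fold's model, and a maximum-margin linear classifier (linear-kernel
#' SVM) is trained on the training scores and evaluated on the held-out
#' scores. The test fold never touches the PCA fit, so there is no
#' information leakage.
#'
#' @param object numeric matrix (spectra in rows) or a [RamanSet-class].
#' @param labels class label per row (2+ classes).
#' @param k number of folds; `k = nrow` gives leave-one-out.
#' @param n_components PCA components kept per fold.
#' @param seed integer seed for the fold shuffle, or `NULL`.
#' @return list with `mean_accuracy`, `fold_accuracy`, `folds` (fold id per
#'   row) and `details` (per-fold PCA centre and training rows, for
#'   leakage audits).
#' @export
kfoldPCAClassify <- function(object, labels, k = 5L, n_components = 5L,
                             seed = NULL) {
  if (is(object, "RamanSet")) object <- intensityMatrix(object)
  X <- object
  n <- nrow(X)
  labels <- factor(labels)
  stopifnot(length(labels) == n, k >= 2L, k <= n)
  folds <- withSeed(seed, {
    f <- integer(n)
    if (k == n) {
      f <- seq_len(n)
    } else {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    f
  })
  for (fold in seq_len(k)) {
    tr <- labels[folds != fold]
    if (length(unique(tr)) < nlevels(labels))
      stop("stratification error: a class is absent from the training set of fold ",
           fold)
  }
  acc <- numeric(k)
  details <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    ncomp <- min(n_components, sum(tr) - 1L, ncol(X))
    pca <- fitPCA(X[tr, , drop = FALSE], n_components = ncomp)
    str <- projectPCA(pca, X[tr, , drop = FALSE])
    ste <- projectPCA(pca, X[!tr, , drop = FALSE])
    fit <- e1071::svm(x = str, y = factor(labels[tr]), kernel = "linear",
                      scale = FALSE)
    pred <- stats::predict(fit, ste)
    acc[fold] <- mean(pred == labels[!tr])
    details[[fold]] <- list(pca_center = pca@center, train_rows = which(tr))
  }
  list(mean_accuracy = mean(acc), fold_accuracy = acc, folds = folds,
       details = details)
}
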