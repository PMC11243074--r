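#' @include AllGenerics.R
NULL

#' Binary PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: the class indicator is coded
#' {0, 1} (second factor level = 1) and latent components are extracted by
#' iterative covariance-maximising deflation (NIPALS). Each spectrum
#' receives `n_components` latent scores; successive score vectors are
#' mutually orthogonal. With a binary response NIPALS needs no inner
#' iteration: each weight vector is the deflated cross-covariance
#' `X' y`, normalised.
#'
#' @param object numeric matrix (spectra in rows) or a [RamanSet-class].
#' @param labels factor-like with exactly two classes.
#' @param n_components latent components (default 5).
#' @param ... unused.
#' @return a [PLSDAModel-class].
#' @export
setMethod("fitPLSDA", "matrix", function(object, labels, n_components = 5L, ...) {
  X <- object
  labels <- droplevels(factor(labels))
  n <- nrow(X)
  if (length(labels) != n) stop("labels must match the number of spectra")
  if (nlevels(labels) != 2L)
    stop("binary PLS-DA needs exactly 2 classes, found ", nlevels(labels))
  if (n < 6L) stop("PLS-DA needs at least 6 spectra")
  y <- as.numeric(labels == levels(labels)[2])
  if (stats::var(y) == 0) stop("class indicator is constant")
  xmu <- colMeans(X)
  ymu <- mean(y)
  E <- sweep(X, 2L, xmu)
  f <- y - ymu
  p <- ncol(X)
  A <- n_components
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pv <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - t * qa
    W[, a] <- w
    P[, a] <- pv
    Tm[, a] <- t
    q[a] <- qa
    a_eff <- a
  }
  if (a_eff == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  Tm <- Tm[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  R <- W %*% solve(crossprod(P, W))
  new("PLSDAModel", x_center = xmu, y_center = ymu, weights = W,
      x_loadings = P, y_loadings = q, projection = R,
      coefficients = drop(R %*% q), scores = Tm, classes = levels(labels))
})

#' @rdname fitPLSDA-matrix-method
#' @export
setMethod("fitPLSDA", "RamanSet", function(object, labels = spectrumLabels(object),
                                           n_components = 5L, ...)
  fitPLSDA(intensityMatrix(object), labels, n_components = n_components))

#' Latent scores of spectra under a PLS-DA model
#'
#' @param model a [PLSDAModel-class].
#' @param newdata numeric matrix (spectra in rows) or a [RamanSet-class].
#' @return score matrix (spectra x components); for the training data this
#'   reproduces the stored NIPALS scores.
#' @export
plsdaScores <- function(model, newdata) {
  if (is(newdata, "RamanSet")) newdata <- intensityMatrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L)
  sweep(newdata, 2L, model@x_center) %*% model@projection
}

#' Continuous PLS-DA prediction of the class indicator
#'
#' @param model a [PLSDAModel-class].
#' @param newdata numeric matrix (spectra in rows) or a [RamanSet-class].
#' @return predicted indicator values (near 0 for the first class, near 1
#'   for the second); used for RMSE.
#' @export
predictPLSDA <- function(model, newdata) {
  if (is(newdata, "RamanSet")) newdata <- intensityMatrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L)
  model@y_center + drop(sweep(newdata, 2L, model@x_center) %*% model@coefficients)
}

#' Mahalanobis binomialization of latent scores
#'
#' Converts multi-dimensional latent scores to a binary call: class
#' centroids are the per-class means of the training scores, the metric is
#' the pooled within-class sample covariance plus a ridge
#' (default `1e-6 * trace / dim`, stabilising near-singular pooled
#' covariances at small n), and each test point goes to the class with the
#' smaller Mahalanobis distance. The continuous decision score is
#' `d(class0) - d(class1)` (distances, not squared), so larger scores favour
#' the second class; it feeds the ROC curve.
#'
#' @param scores_train training score matrix.
#' @param labels_train two-class labels for the training scores.
#' @param scores_test test score matrix.
#' @param ridge_lambda ridge added to the covariance diagonal; `NULL` for
#'   the default, 0 to disable (errors if the covariance is singular).
#' @return list with `predicted` (factor), `decision_score` (numeric,
#'   d0 - d1), `distances` (n x 2) and `classifier`
#'   ([MahalanobisClassifier-class]).
#' @export
mahalanobisBinomialize <- function(scores_train, labels_train, scores_test,
                                   ridge_lambda = NULL) {
  scores_train <- as.matrix(scores_train)
  scores_test <- as.matrix(scores_test)
  labels_train <- droplevels(factor(labels_train))
  if (nlevels(labels_train) != 2L) stop("need exactly two classes")
  d <- ncol(scores_train)
  lv <- levels(labels_train)
  mu <- rbind(colMeans(scores_train[labels_train == lv[1], , drop = FALSE]),
              colMeans(scores_train[labels_train == lv[2], , drop = FALSE]))
  S <- matrix(0, d, d)
  for (cl in lv) {
    Z <- sweep(scores_train[labels_train == cl, , drop = FALSE], 2L,
               mu[match(cl, lv), ])
    S <- S + crossprod(Z)
  }
  S <- S / (nrow(scores_train) - 2L)
  if (is.null(ridge_lambda)) ridge_lambda <- 1e-6 * sum(diag(S)) / d
  Sig <- S + diag(ridge_lambda, d)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled covariance is singular; supply a positive ridge_lambda")
  Sinv <- chol2inv(ch)
  d0 <- sqrt(stats::mahalanobis(scores_test, mu[1, ], Sinv, inverted = TRUE))
  d1 <- sqrt(stats::mahalanobis(scores_test, mu[2, ], Sinv, inverted = TRUE))
  predicted <- factor(ifelse(d1 < d0, lv[2], lv[1]), levels = lv)
  clf <- new("MahalanobisClassifier", centroids = mu, cov_inv = Sinv,
             classes = lv, ridge = ridge_lambda)
  list(predicted = predicted, decision_score = d0 - d1,
       distances = cbind(d0, d1), classifier = clf)
}
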