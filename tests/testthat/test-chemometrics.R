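test_that("PCA matches the covariance eigendecomposition", {
  set.seed(10)
  X <- matrix(rnorm(20 * 50), 20, 50)
  m <- fitPCA(X, n_components = 5L)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(m@evr, ev$values[1:5] / sum(ev$values), tolerance = 1e-8)
  for (j in 1:5)
    expect_equal(abs(sum(m@loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  # full-rank reconstruction of the centred data
  full <- fitPCA(X, n_components = 19L)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(full@scores %*% t(full@loadings), Xc, tolerance = 1e-8)
})

test_that("PCA handles degenerate inputs and fixes signs deterministically", {
  X <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  m <- fitPCA(X, n_components = 2L)
  expect_equal(m@evr, c(0, 0))
  expect_equal(max(abs(m@scores)), 0)
  line <- cbind(1:6, 2 * (1:6))
  m2 <- fitPCA(line, n_components = 2L)
  expect_equal(m2@evr, c(1, 0), tolerance = 1e-12)
  expect_gt(m2@loadings[which.max(abs(m2@loadings[, 1])), 1], 0)
  expect_error(fitPCA(X, n_components = 4L), "n_components")
})

test_that("k-fold PCA classification is perfect on separated classes and honest", {
  b <- blobScores(n = 15, d = 30, sep = 8, seed = 2)
  res <- kfoldPCAClassify(b$x, b$labels, k = 5L, seed = 1)
  expect_equal(res$mean_accuracy, 1)
  expect_length(res$fold_accuracy, 5L)
  # fold honesty: each fold's PCA centre is the mean of its training rows,
  # which differs from the all-data mean
  global <- colMeans(b$x)
  for (f in seq_len(5)) {
    d <- res$details[[f]]
    expect_equal(d$pca_center, colMeans(b$x[d$train_rows, ]),
                 tolerance = 1e-12)
    expect_gt(max(abs(d$pca_center - global)), 0)
  }
})

test_that("k-fold classification of pure noise stays at chance", {
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 40), 60, 40)
    labels <- rep(c("a", "b"), 30)
    kfoldPCAClassify(X, labels, k = 5L, seed = s)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("leave-one-out on four separable points is exact", {
  X <- rbind(c(0, 0), c(0.2, 0), c(10, 0), c(10.2, 0))
  labels <- c("a", "a", "b", "b")
  res <- kfoldPCAClassify(X, labels, k = 4L, n_components = 1L)
  expect_equal(res$mean_accuracy, 1)
})

test_that("PLS-DA extracts the separating direction with orthogonal scores", {
  set.seed(3)
  n <- 20
  X <- matrix(rnorm(2 * n * 10, sd = 0.05), 2 * n, 10)
  X[(n + 1):(2 * n), 4] <- X[(n + 1):(2 * n), 4] + 5
  labels <- rep(c("ctl", "lig"), each = n)
  m <- fitPLSDA(X, labels, n_components = 3L)
  w1 <- m@weights[, 1]
  expect_gt(abs(w1[4]) / sqrt(sum(w1^2)), 0.99)
  # first NIPALS direction is the normalised cross-covariance X_c' y_c
  y <- as.numeric(labels == "lig")
  w_oracle <- crossprod(sweep(X, 2, colMeans(X)), y - mean(y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(sum(w1 * w_oracle)), 1, tolerance = 1e-10)
  # mutual orthogonality of score vectors
  g <- crossprod(m@scores)
  expect_lt(max(abs(g[upper.tri(g)])) / min(diag(g)), 1e-8)
  # training scores equal the projection of the training data
  expect_equal(plsdaScores(m, X), m@scores, tolerance = 1e-8)
  expect_error(fitPLSDA(X, rep("ctl", 2 * n)), "2 classes")
})

test_that("PLS-DA scores are invariant to a constant intensity offset", {
  set.seed(4)
  X <- matrix(rnorm(12 * 8), 12, 8)
  labels <- rep(c("a", "b"), 6)
  m1 <- fitPLSDA(X, labels, n_components = 2L)
  m2 <- fitPLSDA(X + 3.7, labels, n_components = 2L)
  expect_equal(m1@scores, m2@scores, tolerance = 1e-8)
})

test_that("Mahalanobis decisions reduce to Euclidean under isotropic covariance", {
  tr <- exactCovTrain(rbind(c(0, 0), c(5, 1)), 1, 1)
  set.seed(5)
  test <- matrix(rnorm(40, 2, 3), 20, 2)
  mb <- mahalanobisBinomialize(tr$scores, tr$labels, test, ridge_lambda = 0)
  centroids <- rbind(c(0, 0), c(5, 1))
  euclid <- apply(test, 1, function(p) {
    which.min(c(sum((p - centroids[1, ])^2), sum((p - centroids[2, ])^2)))
  })
  expect_identical(as.integer(mb$predicted), as.integer(euclid))
})

test_that("Mahalanobis reproduces the hand-computed two-dimensional case", {
  tr <- exactCovTrain(rbind(c(0, 0), c(4, 0)), 4, 1)
  mb <- mahalanobisBinomialize(tr$scores, tr$labels, rbind(c(1, 0)),
                               ridge_lambda = 0)
  expect_equal(unname(mb$distances[1, ]), c(0.5, 1.5), tolerance = 1e-10)
  expect_identical(as.character(mb$predicted), "a")
  expect_equal(mb$decision_score, 0.5 - 1.5, tolerance = 1e-10)
  at1 <- mahalanobisBinomialize(tr$scores, tr$labels, rbind(c(4, 0)),
                                ridge_lambda = 0)
  expect_identical(as.character(at1$predicted), "b")
  expect_gt(at1$decision_score, 0)
})

test_that("singular pooled covariance demands a ridge", {
  tr <- exactCovTrain(rbind(c(0, 0), c(4, 0)), 4, 1)
  flat <- tr$scores
  flat[, 2] <- 0  # collapse to one dimension
  expect_error(
    mahalanobisBinomialize(flat, tr$labels, rbind(c(1, 0)), ridge_lambda = 0),
    "ridge")
  ok <- mahalanobisBinomialize(flat, tr$labels, rbind(c(1, 0)),
                               ridge_lambda = 1e-6)
  expect_identical(as.character(ok$predicted), "a")
})

test_that("Mahalanobis decisions are affine invariant", {
  set.seed(6)
  tr <- blobScores(n = 15, d = 3, sep = 4, seed = 7)
  test <- matrix(rnorm(30, 2, 2), 10, 3)
  base <- mahalanobisBinomialize(tr$x, tr$labels, test, ridge_lambda = 0)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  b <- c(1, -2, 0.5)
  tfm <- function(M) sweep(M %*% t(A), 2, b, `+`)
  mapped <- mahalanobisBinomialize(tfm(tr$x), tr$labels, tfm(test),
                                   ridge_lambda = 0)
  expect_identical(mapped$predicted, base$predicted)
  expect_equal(mapped$decision_score, base$decision_score, tolerance = 1e-8)
})

test_that("confusion metrics evaluate the printed formulas exactly", {
  m <- confusionMetrics(tp = 30, fp = 0, tn = 0, fn = 0)
  expect_equal(m$sensitivity, 1)
  expect_true(is.na(m$specificity))
  m2 <- confusionMetrics(tp = 10, fp = 1, tn = 49, fn = 0)
  expect_equal(m2$specificity, 0.98)
  m3 <- confusionMetrics(tp = 5, fp = 5, tn = 5, fn = 5)
  expect_equal(m3$accuracy, 0.5)
  expect_error(confusionMetrics(tp = -1, fp = 0, tn = 0, fn = 0),
               "non-negative")
})

test_that("ROC/AUC equals the brute-force rank statistic", {
  perfect <- rocAUC(c(1, 2, 3, 10, 11, 12), rep(c("n", "p"), each = 3))
  expect_equal(perfect@auc, 1)
  ties <- rocAUC(rep(0, 8), rep(c("n", "p"), 4))
  expect_equal(ties@auc, 0.5)
  set.seed(8)
  for (rep in 1:5) {
    s <- sample(round(rnorm(40), 1))  # coarse values force ties
    lab <- sample(rep(c("n", "p"), 20))
    r <- rocAUC(s, lab, positive = "p")
    expect_equal(r@auc, bruteForceAUC(s, lab, "p"), tolerance = 1e-12)
    expect_true(all(diff(r@fpr) >= 0) && all(diff(r@tpr) >= 0))
    expect_equal(c(r@fpr[1], r@tpr[1]), c(0, 0))
    expect_equal(c(r@fpr[length(r@fpr)], r@tpr[length(r@tpr)]), c(1, 1))
    # invariance under a monotone transform of the scores
    expect_equal(rocAUC(exp(s), lab, positive = "p")@auc, r@auc,
                 tolerance = 1e-12)
  }
  expect_error(rocAUC(1:4, rep("p", 4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(60)
  lab <- sample(rep(c("n", "p"), 30))
  ours <- rocAUC(s, lab, positive = "p")@auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, s, levels = c("n", "p"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("rmse evaluates the indicator error", {
  expect_equal(rmse(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(rmse(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(rmse(c(0.1, 0.9, 0.2), c(0, 1, 0)), sqrt(0.02))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("split-sample PLS-DA evaluation is exact on duplicated separable data", {
  b <- blobScores(n = 10, d = 5, sep = 10, seed = 11)
  X <- rbind(b$x, b$x, b$x)  # duplicates force train == test support
  labels <- rep(b$labels, 3)
  ev <- plsdaEvaluate(X, labels, seed = 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_named(ev, c("auc", "rmse", "sensitivity", "specificity", "accuracy",
                     "counts", "roc", "model", "train_idx", "test_idx"),
               ignore.order = TRUE)
})
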