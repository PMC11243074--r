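#' Confusion counts and derived metrics
#'
#' Exact evaluation of the three standard classification metrics from a
#' confusion table: sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
#' accuracy (TP+TN)/(TP+TN+FP+FN). A zero denominator yields `NA` (an
#' undefined metric, never silently 0).
#'
#' @param tp,fp,tn,fn non-negative integer counts, or `tp` may be a list
#'   with those fields.
#' @return list with `sensitivity`, `specificity`, `accuracy` and the
#'   counts.
#' @export
#' @examples
#' confusionMetrics(tp = 30, fp = 1, tn = 49, fn = 0)
confusionMetrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    cc <- tp
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = rat(tp, tp + fn),
       specificity = rat(tn, tn + fp),
       accuracy = rat(tp + tn, tp + tn + fp + fn),
       counts = as.list(counts))
}

#' Tally a confusion table from predictions
#'
#' @param predicted,truth factors on the same two levels.
#' @param positive the positive-class label (default: second level of `truth`).
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(predicted, truth, positive = NULL) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  if (is.null(positive)) positive <- levels(truth)[nlevels(truth)]
  pp <- predicted == positive
  tp <- truth == positive
  list(tp = sum(pp & tp), fp = sum(pp & !tp),
       tn = sum(!pp & !tp), fn = sum(!pp & tp))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores, collecting the
#' false-positive rate (1 - specificity) on the x axis and the
#' true-positive rate on the y axis. Tied scores move the curve diagonally,
#' so the trapezoidal AUC equals the normalised Mann-Whitney rank-sum
#' statistic P(score+ > score-) + P(tie)/2.
#'
#' @param decision_scores numeric; larger favours the positive class.
#' @param true_labels two-class labels.
#' @param positive positive-class label (default: second factor level).
#' @return a [ROCCurve-class].
#' @export
rocAUC <- function(decision_scores, true_labels, positive = NULL) {
  true_labels <- factor(true_labels)
  if (nlevels(true_labels) != 2L)
    stop("ROC needs both classes present")
  if (is.null(positive)) positive <- levels(true_labels)[2]
  y <- true_labels == positive
  if (!any(y) || all(y)) stop("ROC needs both classes present")
  ord <- order(decision_scores, decreasing = TRUE)
  s <- decision_scores[ord]
  yy <- y[ord]
  brk <- which(diff(s) != 0)
  last <- c(brk, length(s))
  ctp <- cumsum(yy)[last]
  cfp <- cumsum(!yy)[last]
  tpr <- c(0, ctp / sum(y))
  fpr <- c(0, cfp / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
      auc = auc)
}

#' Root mean square error of continuous class predictions
#'
#' @param predicted continuous PLS-DA predictions of the class indicator.
#' @param truth the {0, 1} indicator (or a two-level factor).
#' @return non-negative RMSE.
#' @export
#' @examples
#' rmse(c(0.1, 0.9, 0.2), c(0, 1, 0))
rmse <- function(predicted, truth) {
  if (is.factor(truth)) truth <- as.numeric(truth == levels(truth)[2])
  if (!length(predicted)) stop("empty input")
  if (length(predicted) != length(truth)) stop("lengths differ")
  sqrt(mean((predicted - truth)^2))
}

#' Split-sample PLS-DA evaluation
#'
#' The full supervised evaluation in one call: a random 80/20
#' train/test split, PLS-DA fitted on the training spectra only, latent
#' scores binomialized by Mahalanobis nearest centroid, and the held-out
#' partition scored by confusion metrics, ROC/AUC on the continuous
#' distance-difference decision score, and RMSE of the continuous indicator
#' prediction. If a partition misses a class the split is redrawn once,
#' then an error is raised.
#'
#' @param object numeric matrix (spectra in rows) or a [RamanSet-class].
#' @param labels two-class labels per row.
#' @param train_fraction fraction of rows in the training partition.
#' @param n_components PLS latent components.
#' @param ridge_lambda passed to [mahalanobisBinomialize()].
#' @param seed integer seed for the split, or `NULL`.
#' @return list with `auc`, `rmse`, `sensitivity`, `specificity`,
#'   `accuracy`, `counts`, `roc` ([ROCCurve-class]), `model` and the split
#'   indices.
#' @export
plsdaEvaluate <- function(object, labels, train_fraction = 0.8,
                          n_components = 5L, ridge_lambda = NULL,
                          seed = NULL) {
  if (is(object, "RamanSet")) {
    if (missing(labels)) labels <- spectrumLabels(object)
    object <- intensityMatrix(object)
  }
  X <- object
  labels <- factor(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n, train_fraction > 0, train_fraction < 1)
  split_ok <- function(idx) {
    nlevels(droplevels(labels[idx])) == 2L &&
      nlevels(droplevels(labels[-idx])) == 2L
  }
  idx <- withSeed(seed, {
    tr <- sample.int(n, round(train_fraction * n))
    if (!split_ok(tr)) tr <- sample.int(n, round(train_fraction * n))
    tr
  })
  if (!split_ok(idx))
    stop("a partition misses a class even after resampling")
  model <- fitPLSDA(X[idx, , drop = FALSE], labels[idx],
                    n_components = n_components)
  te <- setdiff(seq_len(n), idx)
  mb <- mahalanobisBinomialize(model@scores, labels[idx],
                               plsdaScores(model, X[te, , drop = FALSE]),
                               ridge_lambda = ridge_lambda)
  positive <- levels(labels)[2]
  cc <- confusionCounts(mb$predicted, labels[te], positive = positive)
  cm <- confusionMetrics(cc)
  roc <- rocAUC(mb$decision_score, labels[te], positive = positive)
  err <- rmse(predictPLSDA(model, X[te, , drop = FALSE]), labels[te])
  list(auc = roc@auc, rmse = err, sensitivity = cm$sensitivity,
       specificity = cm$specificity, accuracy = cm$accuracy,
       counts = cc, roc = roc, model = model, train_idx = idx, test_idx = te)
}
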