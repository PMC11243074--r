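#' Delta-F/F summary of a calcium trace
#'
#' The baseline fluorescence F is the mean of the pre-stimulation frames;
#' per-frame delta-F/F is (F(t) - F)/F, and the fold response is the
#' maximum post-stimulation F(t)/F. A non-positive baseline is rejected.
#'
#' @param trace a [CalciumTrace-class].
#' @return list with `dff` (per frame), `f0`, `peak_dff`, `peak_fold`,
#'   `mean_post_ratio`.
#' @export
deltaFOverF <- function(trace) {
  stopifnot(is(trace, "CalciumTrace"))
  t <- trace@time_s
  f <- trace@fluorescence_au
  base <- t < trace@stim_time_s
  f0 <- mean(f[base])
  if (f0 <= 0) stop("non-positive baseline fluorescence")
  post <- t >= trace@stim_time_s
  dff <- (f - f0) / f0
  list(dff = dff, f0 = f0, peak_dff = max(dff[post]),
       peak_fold = max(f[post]) / f0,
       mean_post_ratio = mean(f[post]) / f0)
}

#' Fraction of responding cells
#'
#' Percentage of traces whose post-stimulation fold response strictly
#' exceeds the threshold (default 1.5-fold; a cell at exactly the threshold
#' is not a responder).
#'
#' @param traces list of [CalciumTrace-class], or a numeric vector of fold
#'   responses.
#' @param fold_threshold responder threshold.
#' @return percentage in [0, 100].
#' @export
responderFraction <- function(traces, fold_threshold = 1.5) {
  folds <- if (is.numeric(traces)) traces
           else vapply(traces, function(tr) deltaFOverF(tr)$peak_fold, numeric(1))
  if (!length(folds)) stop("no traces")
  100 * mean(folds > fold_threshold)
}

#' Pooled-variance two-sample t-test
#'
#' Student's (pooled-variance, not Welch) two-sided t-test with
#' n_a + n_b - 2 degrees of freedom, delegated to [stats::t.test()] with
#' degenerate zero-variance inputs handled explicitly: equal means give
#' t = 0, p = 1; unequal means give p = 0 with an infinite statistic and a
#' `degenerate` flag.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
twoSampleT <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = na + nb - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = na + nb - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()]. Zero
#' within-group variance everywhere is flagged as degenerate (F = 0, p = 1
#' when the means also coincide; otherwise an infinite F with p = 0).
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `df`, `p`, `degenerate`.
#' @export
oneWayANOVA <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (within == 0) {
    mu <- vapply(groups, mean, numeric(1))
    if (max(mu) - min(mu) == 0)
      return(list(F = 0, df = c(length(groups) - 1L, length(y) - length(groups)),
                  p = 1, degenerate = TRUE))
    return(list(F = Inf, df = c(length(groups) - 1L, length(y) - length(groups)),
                p = 0, degenerate = TRUE))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1], degenerate = FALSE)
}

#' Tukey HSD post-hoc comparisons
#'
#' Thin wrapper over [stats::TukeyHSD()] on a one-way fit, reported as a
#' data frame of pairwise differences and adjusted p values.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukeyPosthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups)
  if (is.null(nm)) nm <- sprintf("g%d", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  th <- stats::TukeyHSD(stats::aov(y ~ g))$g
  data.frame(comparison = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"],
             row.names = NULL)
}

#' Weighted pool-adjacent-violators isotonic regression
#'
#' Monotone non-decreasing estimates of a sequence of means under weights
#' (group sizes): adjacent violators are amalgamated into weighted averages.
#' The weighted grand mean is preserved.
#'
#' @param x numeric values (e.g. group means, in dose order).
#' @param w positive weights (e.g. group sizes).
#' @return isotonic values, same length as `x`.
#' @export
#' @examples
#' pava(c(1, 3, 2))  # -> 1, 2.5, 2.5
pava <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w > 0))
  n <- length(x)
  if (n <= 1L) return(x)
  val <- x
  wt <- w
  cnt <- rep(1L, n)
  m <- n
  i <- 1L
  while (i < m) {
    if (val[i] > val[i + 1L]) {
      val[i] <- (wt[i] * val[i] + wt[i + 1L] * val[i + 1L]) /
        (wt[i] + wt[i + 1L])
      wt[i] <- wt[i] + wt[i + 1L]
      cnt[i] <- cnt[i] + cnt[i + 1L]
      val <- val[-(i + 1L)]
      wt <- wt[-(i + 1L)]
      cnt <- cnt[-(i + 1L)]
      m <- m - 1L
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  rep(val, cnt)
}
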