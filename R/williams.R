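# Williams-type statistics for one simulated or observed design.
# Returns the t-bar statistic at every dose given raw group data
# (list: control first, then doses ascending).
williamsStatistics <- function(groups) {
  k <- length(groups) - 1L
  n <- lengths(groups)
  mu <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - length(groups))
  iso <- pava(mu[-1], w = n[-1])
  (iso - mu[1]) / sqrt(s2 * (1 / n[-1] + 1 / n[1]))
}

#' Monte-Carlo critical value for the Williams trend statistic
#'
#' Simulates the null (all group means equal, unit-variance normal data on
#' the given n-structure), applies the same isotonic amalgamation and
#' studentisation as the test itself, and returns the upper
#' `1 - alpha` quantile of the top-dose statistic. Simulation replaces the
#' printed tables because those cover few (k, n) combinations; the same
#' seeded machinery is reused by the calibration tests.
#'
#' @param n_control control group size.
#' @param n_treated treated group sizes in dose order.
#' @param alpha one-sided significance level.
#' @param n_null Monte-Carlo replicates.
#' @param seed integer seed, or `NULL`.
#' @return critical value for the statistic at the highest dose.
#' @export
williamsCriticalValue <- function(n_control, n_treated, alpha = 0.05,
                                  n_null = 10000L, seed = NULL) {
  stopifnot(n_control >= 2L, all(n_treated >= 2L), n_null >= 100L)
  sizes <- c(n_control, n_treated)
  withSeed(seed, {
    stat <- numeric(n_null)
    for (r in seq_len(n_null)) {
      sim <- lapply(sizes, stats::rnorm)
      tb <- williamsStatistics(sim)
      stat[r] <- tb[length(tb)]
    }
    unname(stats::quantile(stat, 1 - alpha, type = 7))
  })
}

#' Williams-type step-down trend test against control
#'
#' Tests ordered dose groups against the control under a monotone
#' non-decreasing mean assumption. Group means are replaced by isotonic
#' (pooled-adjacent-violators, weighted by n) estimates over the treated
#' groups; the statistic at dose i is
#' `(mu_iso_i - mean_control) / sqrt(s2 (1/n_i + 1/n_0))` with `s2` the
#' pooled within-group (ANOVA) variance. Critical values come from seeded
#' Monte-Carlo simulation of the matching null design, and testing steps
#' down from the highest dose: a dose is declared significant only if every
#' higher dose is, per Williams's closed testing scheme.
#'
#' @param values numeric response values.
#' @param doses dose (uM) per value; the smallest dose is the control and
#'   must come first in `dose_levels` order.
#' @param dose_levels optional explicit dose ordering (ascending; first is
#'   control). Defaults to the sorted unique doses.
#' @param alpha one-sided significance level.
#' @param n_null Monte-Carlo replicates per critical value.
#' @param seed integer seed for the simulation, or `NULL`.
#' @return list with `table` (data.frame: dose, n, mean, isotonic_mean,
#'   t_bar, critical, significant), `s2`, `df`, `alpha`.
#' @export
williamsTrendTest <- function(values, doses, dose_levels = NULL,
                              alpha = 0.05, n_null = 10000L, seed = NULL) {
  stopifnot(length(values) == length(doses))
  if (is.null(dose_levels)) dose_levels <- sort(unique(doses))
  if (is.unsorted(dose_levels, strictly = TRUE))
    stop("dose_levels must be strictly increasing with the control first")
  if (!setequal(dose_levels, unique(doses)))
    stop("dose_levels must cover exactly the observed doses")
  groups <- lapply(dose_levels, function(d) values[doses == d])
  if (any(lengths(groups) < 2L)) stop("each dose group needs at least 2 values")
  k <- length(groups) - 1L
  if (k < 1L) stop("need at least one treated dose beyond the control")
  n <- lengths(groups)
  mu <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - (k + 1L))
  if (s2 == 0) stop("zero pooled within-group variance")
  iso <- pava(mu[-1], w = n[-1])
  tbar <- (iso - mu[1]) / sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  crit <- vapply(seq_len(k), function(i) {
    williamsCriticalValue(n[1], n[2:(i + 1L)], alpha = alpha,
                          n_null = n_null,
                          seed = if (is.null(seed)) NULL else seed + i)
  }, numeric(1))
  exceeds <- tbar > crit
  significant <- rev(cumprod(rev(exceeds))) > 0  # step-down from the top
  list(table = data.frame(dose_um = dose_levels[-1], n = n[-1],
                          mean = mu[-1], isotonic_mean = iso, t_bar = tbar,
                          critical = crit, significant = significant),
       control_mean = mu[1], n_control = n[1], s2 = s2, df = N - (k + 1L),
       alpha = alpha)
}
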