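# Shared fixtures built in code; nothing is stored on disk.

# A small flat-baseline one-band design for analytic checks.
oneBandDesign <- function(noise_scale = 0, amplitude = 1, center = 1001,
                          width = 12, multiplier = 1) {
  syntheticDesign(
    bands = data.frame(center_cm1 = center, width_cm1 = width,
                       amplitude = amplitude, effect_multiplier = multiplier),
    baseline_coeffs = 0, noise_scale = noise_scale, spike_rate = 0)
}

# Deterministic well-separated 2-class score clouds for classifier checks.
blobScores <- function(n = 20, d = 2, sep = 6, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d), n, d) + c(rep(sep, n), rep(0, n * (d - 1))))
    list(x = x, labels = factor(rep(c("a", "b"), each = n)))
  })
}

# Training scores whose pooled within-class covariance is exactly
# diag(v1, v2): per-class offsets (+-b, 0), (0, +-c) around each centroid.
exactCovTrain <- function(centroids, v1, v2) {
  b <- sqrt(v1 * 6 / 4)
  c <- sqrt(v2 * 6 / 4)
  off <- rbind(c(b, 0), c(-b, 0), c(0, c), c(0, -c))
  list(scores = rbind(sweep(off, 2, centroids[1, ], `+`),
                      sweep(off, 2, centroids[2, ], `+`)),
       labels = factor(rep(c("a", "b"), each = 4)))
}

# Brute-force pairwise rank AUC: P(score+ > score-) + P(tie)/2.
bruteForceAUC <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
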