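test_that("despiking removes injected spikes and nothing else", {
  cfg <- preprocessConfig(despike = TRUE)
  set.seed(1)
  clean <- 10 + rnorm(400, sd = 0.1)
  expect_identical(despike(clean, cfg), clean)
  spiked <- clean
  spiked[200] <- spiked[200] + 50 * 0.1
  fixed <- despike(spiked, cfg)
  expect_lt(abs(fixed[200] - clean[200]), 3 * 0.1)
  expect_identical(fixed[-200], spiked[-200])
  const <- rep(5, 100)
  expect_identical(despike(const, cfg), const)
  broken <- clean
  broken[seq(1, 400, 5)] <- broken[seq(1, 400, 5)] + 100
  expect_error(despike(broken, cfg), "5%")
})

test_that("a spike-free generated spectrum passes through despiking unchanged", {
  d <- syntheticDesign(noise_scale = 0.02)
  sp <- generateSpectrum(d, seed = 8)
  expect_identical(intensities(despike(sp)), intensities(sp))
})

test_that("order-2 Savitzky-Golay reproduces quadratics exactly", {
  x <- seq_len(101)
  quad <- 3 + 0.5 * x - 0.02 * x^2
  for (w in c(5L, 7L, 11L, 25L)) {
    cfg <- preprocessConfig(sg_window = w)
    expect_lt(max(abs(sgSmooth(quad, cfg) - quad)), 1e-9)
  }
  const <- rep(2.5, 50)
  expect_equal(sgSmooth(const), const, tolerance = 1e-12)
  expect_error(sgSmooth(rnorm(5), preprocessConfig(sg_window = 7L)), "length")
  expect_error(preprocessConfig(sg_window = 10L), "odd")
})

test_that("window-5 interior weights match the brute-force local fit", {
  # brute force: order-2 least squares on offsets -2..2, evaluated at 0
  V <- outer(-2:2, 0:2, `^`)
  H <- V %*% solve(crossprod(V)) %*% t(V)
  expect_equal(H[3, ], c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  # impulse response of the smoother at an interior point gives its weights
  cfg <- preprocessConfig(sg_window = 5L)
  weights <- vapply(0:4, function(k) {
    e <- rep(0, 21)
    e[9 + k] <- 1
    sgSmooth(e, cfg)[11]
  }, numeric(1))
  expect_equal(weights, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
})

test_that("order-4 polynomial baselines are removed to numerical precision", {
  x <- seq(46, 3110, by = 2)
  u <- 2 * (x - min(x)) / diff(range(x)) - 1
  base <- 5 - 1.5 * u + u^2 + 0.4 * u^3 - 0.5 * u^4
  res <- baselineCorrect(base, x)
  expect_lt(max(abs(res$corrected)), 1e-6 * max(abs(base)))
  expect_true(res$converged)
  zero <- baselineCorrect(rep(0, 100), seq_len(100))
  expect_identical(zero$corrected, rep(0, 100))
  expect_identical(zero$baseline, rep(0, 100))
})

test_that("band heights survive baseline removal within 5%", {
  d <- syntheticDesign(
    bands = data.frame(center_cm1 = c(800, 1450, 2900),
                       width_cm1 = c(12, 15, 20), amplitude = c(1, 0.6, 0.8),
                       effect_multiplier = 1),
    noise_scale = 0)
  sp <- generateSpectrum(d, seed = 1)
  res <- baselineCorrect(intensities(sp), wavenumbers(sp))
  idx <- vapply(c(800, 1450, 2900),
                function(m) which.min(abs(wavenumbers(sp) - m)), 1L)
  expect_equal(res$corrected[idx], c(1, 0.6, 0.8), tolerance = 0.05)
})

test_that("baseline correction is idempotent on its own output", {
  # run both passes deep into the clipped-refit fixed point: the second
  # pass's baseline must collapse to zero
  d <- syntheticDesign(noise_scale = 0.02)
  sp <- generateSpectrum(d, seed = 3)
  cfg <- preprocessConfig(baseline_tol = 1e-12, baseline_max_iter = 500L)
  first <- suppressWarnings(baselineCorrect(intensities(sp), wavenumbers(sp), cfg))
  second <- suppressWarnings(baselineCorrect(first$corrected, wavenumbers(sp), cfg))
  expect_lt(max(abs(second$baseline)), 1e-6 * max(abs(intensities(sp))))
})

test_that("crop and vector normalization yields unit norm and scale invariance", {
  d <- syntheticDesign(noise_scale = 0.02)
  sp <- generateSpectrum(d, seed = 4)
  out <- cropAndVectorNormalize(sp)
  expect_equal(sqrt(sum(intensities(out)^2)), 1, tolerance = 1e-12)
  expect_true(all(wavenumbers(out) >= 600 & wavenumbers(out) <= 2980))
  scaled <- RamanSpectrum(wavenumbers(sp), 10 * intensities(sp))
  expect_equal(intensities(cropAndVectorNormalize(scaled)), intensities(out),
               tolerance = 1e-12)
  outside <- RamanSpectrum(seq(100, 500, 10), rep(1, 41))
  expect_error(cropAndVectorNormalize(outside), "misses the grid")
  zero <- rep(0, 100)
  expect_error(cropAndVectorNormalize(zero, seq(601, 700, along.with = zero)),
               "zero")
})

test_that("pipeline preserves labels, normalizes rows, and keeps band positions", {
  d <- oneBandDesign(noise_scale = 0.005)
  d@baseline_coeffs <- c(5, -1.5, 1, 0.4, -0.5)
  set <- generateDataset(syntheticDesign(noise_scale = 0.02, n_per_group = 5L),
                         "two_class", seed = 6)
  pp <- preprocessPipeline(set)
  expect_identical(spectrumLabels(pp), spectrumLabels(set))
  expect_identical(spectrumDoses(pp), spectrumDoses(set))
  norms <- unname(sqrt(rowSums(intensityMatrix(pp)^2)))
  expect_equal(norms, rep(1, 10), tolerance = 1e-12)
  # noiseless one-band set: band position unchanged within one grid step
  one <- oneBandDesign()
  one@baseline_coeffs <- c(5, -1.5, 1, 0.4, -0.5)
  validObject(one)
  oneset <- generateDataset(
    syntheticDesign(bands = one@bands, baseline_coeffs = one@baseline_coeffs,
                    noise_scale = 0, n_per_group = 2L),
    "two_class", seed = 1)
  ppo <- preprocessPipeline(oneset)
  g <- wavenumbers(ppo)
  peak <- g[which.max(intensityMatrix(ppo)[1, ])]
  expect_lt(abs(peak - 1001), 1.5 * diff(g[1:2]))
})

test_that("pipeline output is invariant to uniform intensity rescaling", {
  set <- generateDataset(syntheticDesign(noise_scale = 0.02, n_per_group = 3L),
                         "two_class", seed = 2)
  scaled <- RamanSet(wavenumbers(set), 7.3 * intensityMatrix(set),
                     labels = spectrumLabels(set),
                     doses_um = spectrumDoses(set))
  expect_equal(intensityMatrix(preprocessPipeline(set)),
               intensityMatrix(preprocessPipeline(scaled)), tolerance = 1e-9)
})

test_that("pipeline errors are annotated with the failing spectrum", {
  d <- syntheticDesign(noise_scale = 0.02)
  g <- d@grid_cm1
  # row 2 is identically zero: nothing survives normalization
  m <- rbind(intensities(generateSpectrum(d, seed = 1)), rep(0, length(g)))
  set <- RamanSet(g, m, labels = c("a", "b"))
  expect_error(preprocessPipeline(set), "spectrum 2")
})
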