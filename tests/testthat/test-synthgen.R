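test_that("Hill effect fraction matches its closed form", {
  d <- syntheticDesign()
  expect_identical(effectFraction(0, d), 0)
  expect_equal(effectFraction(d@ec50_um, d), d@emax / 2, tolerance = 1e-12)
  expect_equal(effectFraction(c(0.05, 0.5, 5, 50, 500), d),
               c(0.05, 0.5, 5, 50, 500) / (0.5 + c(0.05, 0.5, 5, 50, 500)),
               tolerance = 1e-12)
  expect_equal(effectFraction(0.05, d), 0.0909, tolerance = 1e-3)
  expect_error(effectFraction(-1, d), "non-negative")
  dose <- sort(runif(20, 0, 100))
  expect_true(all(diff(effectFraction(dose, d)) >= 0))
})

test_that("noiseless one-band spectrum is the exact analytic profile", {
  d <- oneBandDesign()
  sp <- generateSpectrum(d, seed = 1)
  g <- d@grid_cm1
  expect_equal(intensities(sp), 1 / (1 + ((g - 1001) / 6)^2), tolerance = 1e-12)
})

test_that("generators are pure functions of their seed", {
  d <- syntheticDesign(noise_scale = 0.05, spike_rate = 0.5)
  a <- generateSpectrum(d, seed = 42)
  b <- generateSpectrum(d, seed = 42)
  expect_identical(intensities(a), intensities(b))
  s1 <- generateDataset(d, seed = 9)
  s2 <- generateDataset(d, seed = 9)
  expect_identical(intensityMatrix(s1), intensityMatrix(s2))
  # and they restore the ambient RNG stream
  set.seed(123)
  before <- .Random.seed
  invisible(generateSpectrum(d, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("marker-band fold change is recovered by least squares", {
  d <- syntheticDesign(noise_scale = 0.01, n_per_group = 30L)
  # joint least squares on known band profiles + baseline basis
  X <- cbind(neuroraman:::bandProfiles(d),
             neuroraman:::orthPolyBasis(d@grid_cm1, 4))
  marker <- which(d@bands$effect_multiplier == 1.5)
  set <- generateDataset(d, "two_class", ligand_dose_um = 1e6, seed = 11)
  m0 <- colMeans(intensityMatrix(set)[1:30, ])    # control, effect 0
  m1 <- colMeans(intensityMatrix(set)[31:60, ])   # ligand, effect ~ 1
  r0 <- qr.solve(X, m0)[marker]
  r1 <- qr.solve(X, m1)[marker]
  expect_equal(unname(r1 / r0), rep(1.5, length(marker)), tolerance = 0.05)
})

test_that("dataset bookkeeping matches the experimental designs", {
  d <- syntheticDesign(n_per_group = 30L)
  tc <- generateDataset(d, "two_class", seed = 1)
  expect_equal(ncol(tc), 60L)
  expect_equal(as.vector(table(spectrumLabels(tc))), c(30L, 30L))
  ds <- generateDataset(d, "dose_series", seed = 1)
  expect_equal(ncol(ds), 180L)
  expect_equal(sort(unique(spectrumDoses(ds))), c(0, 0.05, 0.5, 5, 50, 500))
  expect_equal(as.vector(table(spectrumDoses(ds))), rep(30L, 6))
})

test_that("ganglion averaging shrinks residual noise like 1/sqrt(k)", {
  d <- syntheticDesign(noise_scale = 0.05, n_per_group = 50L)
  clean <- neuroraman:::cleanSignal(d, 0)
  sdResidual <- function(set)
    mean(apply(sweep(intensityMatrix(set), 2, clean), 1, sd))
  single <- sdResidual(generateDataset(d, "two_class", ligand_dose_um = 0,
                                       seed = 3))
  gang <- sdResidual(generateDataset(d, "two_class", ligand_dose_um = 0,
                                     ganglion = TRUE, k_cells = 10L, seed = 3))
  expect_equal(gang / single, 1 / sqrt(10), tolerance = 0.2)
})

test_that("marker-band intensity is non-decreasing in dose (noiseless)", {
  d <- syntheticDesign(noise_scale = 0)
  markers <- d@bands$center_cm1[d@bands$effect_multiplier > 1]
  prev <- -Inf
  for (dose in d@dose_grid_um) {
    sp <- generateSpectrum(d, dose_um = dose, seed = 1)
    idx <- vapply(markers, function(m) which.min(abs(d@grid_cm1 - m)), 1L)
    v <- sum(intensities(sp)[idx])
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("empty band table and bad parameters are rejected", {
  expect_error(syntheticDesign(bands = defaultBandTable()[0, ]), "empty")
  expect_error(syntheticDesign(ec50_um = -1), "ec50")
  expect_error(syntheticDesign(n_per_group = 1), "n_per_group")
  bad <- defaultBandTable()
  bad$center_cm1[1] <- 4000
  expect_error(syntheticDesign(bands = bad), "46-3110")
})

test_that("sulfur reference places its five lines where printed", {
  sul <- generateSulfurReference()
  pk <- detectPeaks(sul$spectrum, min_prominence_frac = 0.1)
  step <- diff(wavenumbers(sul$spectrum)[1:2])
  expect_equal(nrow(pk), 5L)
  expect_true(all(abs(pk$position - c(50.0, 85.1, 153.8, 219.1, 473.2)) < step))
  expect_error(generateSulfurReference(distortion = function(v) -v),
               "monotone")
})

test_that("calcium traces follow the dose-response and the calcium-free null", {
  d <- syntheticDesign()
  cal <- calciumDesign()
  foldAt <- function(dose, design = cal, seed = 7) {
    tr <- generateCalciumTraces(design, dose, d, seed = seed)
    vapply(tr, function(x) deltaFOverF(x)$peak_fold, numeric(1))
  }
  expect_equal(mean(foldAt(0)), 1, tolerance = 0.1)
  expect_gte(mean(foldAt(500) > 1.5), 0.9)
  nofree <- calciumDesign(calcium_present = FALSE)
  expect_lte(responderFraction(generateCalciumTraces(nofree, 500, d, seed = 7)),
             5)
  a <- generateCalciumTraces(cal, 5, d, seed = 4)
  b <- generateCalciumTraces(cal, 5, d, seed = 4)
  expect_identical(a[[3]]@fluorescence_au, b[[3]]@fluorescence_au)
})
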