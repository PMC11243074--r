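test_that("two-column and CSV spectra round-trip bit exactly", {
  sp <- generateSpectrum(syntheticDesign(noise_scale = 0.05), seed = 2)
  for (fmt in c("table", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", if (fmt == "csv") "csv" else "txt"))
    writeSpectrum(sp, f, format = fmt)
    back <- readSpectrum(f)
    expect_identical(wavenumbers(back), wavenumbers(sp))
    expect_identical(intensities(back), intensities(sp))
  }
})

test_that("descending axes are reversed into ascending convention", {
  f <- withr::local_tempfile(fileext = ".txt")
  x <- seq(100, 40, by = -2)
  y <- seq_along(x)
  writeLines(sprintf("%g %g", x, y), f)
  sp <- readSpectrum(f)
  expect_identical(wavenumbers(sp), rev(x))
  expect_identical(intensities(sp), as.numeric(rev(y)))
})

test_that("format errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(sprintf("%d %d", 1:20, 1:20), "21 oops"), f)
  expect_error(readSpectrum(f), "line 21.*non-numeric")
  writeLines(c(sprintf("%d %d", 1:20, 1:20), "21 1 9"), f)
  expect_error(readSpectrum(f), "line 21.*2 columns")
  writeLines(sprintf("%d %d", 1:10, 1:10), f)
  expect_error(readSpectrum(f), "16 points")
})

test_that("JCAMP-DX with X/Y factors matches its unscaled CSV twin", {
  sp <- generateSpectrum(syntheticDesign(noise_scale = 0.02), seed = 5)
  fj <- withr::local_tempfile(fileext = ".jdx")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeSpectrum(sp, fj, format = "jcampdx", xfactor = 0.5, yfactor = 2e-3)
  writeSpectrum(sp, fc, format = "csv")
  a <- readSpectrum(fj)
  b <- readSpectrum(fc)
  expect_equal(wavenumbers(a), wavenumbers(b), tolerance = 1e-9)
  expect_equal(intensities(a), intensities(b), tolerance = 1e-9)
})

test_that("RamanSet CSV round-trips with labels and doses", {
  set <- generateDataset(syntheticDesign(n_per_group = 3L), "dose_series",
                         seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeRamanSet(set, f)
  back <- readRamanSet(f)
  expect_identical(unname(intensityMatrix(back)), unname(intensityMatrix(set)))
  expect_identical(spectrumLabels(back), spectrumLabels(set))
  expect_identical(spectrumDoses(back), spectrumDoses(set))
})

test_that("three-anchor calibration interpolates exactly", {
  anchors <- c(153.8, 219.1, 473.2)
  cal <- calibrateWavenumbers(anchors, anchors)
  expect_equal(cal@residuals, rep(0, 3), tolerance = 1e-9)
  expect_equal(applyCalibration(cal, c(100, 300)), c(100, 300),
               tolerance = 1e-9)
  shift <- calibrateWavenumbers(anchors + 5, anchors)
  expect_equal(shift@residuals, rep(0, 3), tolerance = 1e-9)
  expect_equal(applyCalibration(shift, anchors + 5), anchors,
               tolerance = 1e-9)
  expect_error(calibrateWavenumbers(153.8, 153.8), "at least 2")
  expect_error(calibrateWavenumbers(c(100, 90, 300), anchors), "increasing")
})

test_that("quadratic axis distortion is recovered within 0.5 cm-1", {
  distortion <- function(v) v + 2 + 2e-5 * (v - 46)^2
  sul <- generateSulfurReference(distortion = distortion)
  pk <- detectPeaks(sul$spectrum, min_prominence_frac = 0.1)
  expect_equal(nrow(pk), 5L)
  anchor_ref <- c(153.8, 219.1, 473.2)
  cal <- calibrateWavenumbers(pk$position[3:5], anchor_ref)
  recovered <- applyCalibration(cal, pk$position)
  expect_true(all(abs(recovered - sul$true_peaks) < 0.5))
})

test_that("with more than three anchors the quadratic is the least-squares fit", {
  obs <- c(50, 85.1, 153.8, 219.1, 473.2)
  ref <- obs + 3 + 1e-4 * (obs - 50)^2 + rep(c(0.05, -0.05), length.out = 5)
  cal <- calibrateWavenumbers(obs, ref)
  ls <- lm(ref ~ obs + I(obs^2))
  expect_equal(cal@rms, sqrt(mean(residuals(ls)^2)), tolerance = 1e-9)
  expect_gt(cal@rms, 0)
})

test_that("resampling is linear interpolation with guarded extrapolation", {
  d <- oneBandDesign()
  sp <- generateSpectrum(d, seed = 1)
  same <- resampleToGrid(sp, wavenumbers(sp))
  expect_identical(intensities(same), intensities(sp))
  ramp <- RamanSpectrum(seq(0, 100, 5), 2 * seq(0, 100, 5) + 1)
  fine <- resampleToGrid(ramp, seq(2.5, 97.5, 2.5))
  expect_equal(intensities(fine), 2 * seq(2.5, 97.5, 2.5) + 1,
               tolerance = 1e-12)
  # halve resolution, restore: smooth band error below 1% of peak height
  g <- seq(800, 1200, by = 0.5)
  band <- RamanSpectrum(g, 1 / (1 + ((g - 1001) / 6)^2))
  coarse <- resampleToGrid(band, g[seq(1, length(g), 2)])
  keep <- g >= min(g) & g <= max(wavenumbers(coarse))
  restored <- resampleToGrid(coarse, g[keep])
  err <- max(abs(intensities(restored) - intensities(band)[keep]))
  expect_lt(err, 0.01 * max(intensities(band)))
  expect_error(resampleToGrid(sp, c(0, 100)), "extrapolation")
})
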