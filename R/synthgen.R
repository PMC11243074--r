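#' Default Raman band table for synthetic neuron spectra
#'
#' Band positions follow the assignments observed in cultured neurons and
#' ganglia: nucleic-acid bands (740, 748, 1337 cm^-1), protein bands (994,
#' 1001, 1126, 1337, 1447, 1585, 1660 cm^-1, amide I region around 1630),
#' and lipid bands (1126, 1301, 1447, 1660, 2848, 2930 cm^-1). The
#' ligand-response marker bands at 740, 994, 1121 and 2848 cm^-1 carry an
#' amplitude fold-change of 1.5 at full effect; the amide I region
#' (1592-1668 cm^-1) a smaller 1.2. Widths are FWHM in cm^-1; amplitudes
#' arbitrary units on the scale of a vector-unnormalized cell spectrum.
#'
#' @return `data.frame` with columns `center_cm1`, `width_cm1`, `amplitude`,
#'   `effect_multiplier`.
#' @export
defaultBandTable <- function() {
  data.frame(
    center_cm1 = c(740, 748, 994, 1001, 1121, 1126, 1301, 1337,
                   1447, 1585, 1630, 1660, 2848, 2930),
    width_cm1 = c(12, 14, 12, 10, 14, 14, 18, 18, 18, 16, 40, 20, 30, 40),
    amplitude = c(0.35, 0.55, 0.30, 1.00, 0.30, 0.55, 0.50, 0.60,
                  0.80, 0.45, 0.55, 0.70, 0.60, 1.20),
    effect_multiplier = c(1.5, 1, 1.5, 1, 1.5, 1, 1, 1, 1, 1, 1.2, 1, 1.5, 1))
}

#' Generative design for synthetic Raman datasets
#'
#' Full specification of the synthetic spectrum generator: Lorentzian bands
#' over a slowly varying polynomial fluorescence baseline, shot-noise-like
#' Gaussian noise whose standard deviation scales with sqrt(signal + 1),
#' optional single-pixel cosmic-ray spikes, and a Hill dose-response that
#' scales the marker-band amplitudes. Defaults mirror the study conditions:
#' instrument grid 46-3110 cm^-1, dose grid 0/0.05/0.5/5/50/500 uM, 30
#' spectra per condition.
#'
#' @slot bands band table as from [defaultBandTable()].
#' @slot baseline_coeffs polynomial coefficients (ascending powers) of the
#'   fluorescence baseline, evaluated on the grid mapped to [-1, 1].
#' @slot noise_scale multiplicative shot-noise coefficient.
#' @slot spike_rate expected cosmic-ray spikes per spectrum (Poisson).
#' @slot spike_amplitude_range additive spike amplitude range (a.u.).
#' @slot dose_grid_um non-negative sorted doses in micromolar.
#' @slot emax,ec50_um,hill_h Hill dose-response parameters.
#' @slot n_per_group spectra per condition.
#' @slot grid_cm1 strictly increasing wavenumber grid.
#' @slot seed integer seed making every generator call reproducible.
#' @export
setClass("SyntheticDesign",
         representation(bands = "data.frame", baseline_coeffs = "numeric",
                        noise_scale = "numeric", spike_rate = "numeric",
                        spike_amplitude_range = "numeric",
                        dose_grid_um = "numeric", emax = "numeric",
                        ec50_um = "numeric", hill_h = "numeric",
                        n_per_group = "integer", grid_cm1 = "numeric",
                        seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  b <- object@bands
  need <- c("center_cm1", "width_cm1", "amplitude", "effect_multiplier")
  if (!all(need %in% names(b))) return("bands must have the BandSpec columns")
  if (nrow(b) == 0L) return("band list must not be empty")
  if (any(b$center_cm1 < 46 | b$center_cm1 > 3110))
    return("band centers must lie in the instrument range 46-3110 cm-1")
  if (any(b$width_cm1 <= 0)) return("band widths must be positive")
  if (any(b$amplitude < 0)) return("band amplitudes must be non-negative")
  if (any(b$effect_multiplier <= 0)) return("effect multipliers must be positive")
  if (any(object@dose_grid_um < 0)) return("doses must be non-negative")
  if (is.unsorted(object@dose_grid_um, strictly = TRUE)) return("dose grid must be sorted")
  if (object@ec50_um <= 0) return("ec50 must be positive")
  if (object@hill_h <= 0) return("Hill coefficient must be positive")
  if (object@emax < 0) return("emax must be non-negative")
  if (object@n_per_group < 2L) return("n_per_group must be at least 2")
  if (any(diff(object@grid_cm1) <= 0)) return("grid must be strictly increasing")
  if (length(object@spike_amplitude_range) != 2L ||
      any(object@spike_amplitude_range < 0) ||
      diff(object@spike_amplitude_range) < 0)
    return("spike_amplitude_range must be an increasing non-negative pair")
  if (object@spike_rate < 0) return("spike_rate must be non-negative")
  if (object@noise_scale < 0) return("noise_scale must be non-negative")
  TRUE
})

#' @param bands,baseline_coeffs,noise_scale,spike_rate,spike_amplitude_range
#'   see slots.
#' @param dose_grid_um,emax,ec50_um,hill_h,n_per_group,grid_cm1,seed see slots.
#' @rdname SyntheticDesign-class
#' @export
syntheticDesign <- function(bands = defaultBandTable(),
                            baseline_coeffs = c(5, -1.5, 1.0, 0.4, -0.5),
                            noise_scale = 0.02,
                            spike_rate = 0,
                            spike_amplitude_range = c(5, 50),
                            dose_grid_um = c(0, 0.05, 0.5, 5, 50, 500),
                            emax = 1, ec50_um = 0.5, hill_h = 1,
                            n_per_group = 30L,
                            grid_cm1 = seq(46, 3110, by = 2),
                            seed = 1L) {
  new("SyntheticDesign", bands = bands, baseline_coeffs = baseline_coeffs,
      noise_scale = noise_scale, spike_rate = spike_rate,
      spike_amplitude_range = spike_amplitude_range,
      dose_grid_um = as.numeric(dose_grid_um), emax = emax, ec50_um = ec50_um,
      hill_h = hill_h, n_per_group = as.integer(n_per_group),
      grid_cm1 = as.numeric(grid_cm1), seed = as.integer(seed))
}

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(paste0("SyntheticDesign: %d bands on %d-point grid; ",
                     "noise %.3g, spikes %.3g/spectrum\n"),
              nrow(object@bands), length(object@grid_cm1),
              object@noise_scale, object@spike_rate))
  cat(sprintf("  Hill: emax %.3g, ec50 %.3g uM, h %.3g; doses %s uM; n %d/group\n",
              object@emax, object@ec50_um, object@hill_h,
              paste(object@dose_grid_um, collapse = "/"), object@n_per_group))
})

#' Hill fractional effect at a dose
#'
#' Saturating dose-response emax * dose^h / (ec50^h + dose^h): zero at dose
#' zero, emax/2 at the ec50 when h = 1, monotone non-decreasing.
#'
#' @param dose_um dose(s) in micromolar, non-negative.
#' @param design a [SyntheticDesign-class] supplying emax, ec50 and h.
#' @return fractional effect in [0, emax].
#' @export
#' @examples
#' effectFraction(c(0, 0.5, 500), syntheticDesign())
effectFraction <- function(dose_um, design = syntheticDesign()) {
  if (any(dose_um < 0)) stop("dose must be non-negative")
  h <- design@hill_h
  design@emax * dose_um^h / (design@ec50_um^h + dose_um^h)
}

# Lorentzian (Cauchy) unit-height profile matrix: grid points x bands.
bandProfiles <- function(design) {
  b <- design@bands
  g <- design@grid_cm1
  P <- matrix(0, length(g), nrow(b))
  for (j in seq_len(nrow(b)))
    P[, j] <- 1 / (1 + ((g - b$center_cm1[j]) / (b$width_cm1[j] / 2))^2)
  P
}

# Fluorescence baseline evaluated on the design grid.
baselineCurve <- function(design) {
  g <- design@grid_cm1
  u <- 2 * (g - min(g)) / diff(range(g)) - 1
  drop(outer(u, seq_along(design@baseline_coeffs) - 1, `^`) %*%
         design@baseline_coeffs)
}

# Noiseless signal (baseline + effect-scaled bands) at a fractional effect.
cleanSignal <- function(design, effect = 0) {
  amps <- design@bands$amplitude *
    (1 + effect * (design@bands$effect_multiplier - 1))
  baselineCurve(design) + drop(bandProfiles(design) %*% amps)
}

# Adds shot-like noise and Poisson cosmic-ray spikes to a clean signal
# matrix (rows = spectra). Consumes the current RNG stream.
addNoiseAndSpikes <- function(design, clean) {
  n <- nrow(clean)
  p <- ncol(clean)
  sdm <- design@noise_scale * sqrt(pmax(clean, 0) + 1)
  out <- clean + matrix(stats::rnorm(n * p), n, p) * sdm
  if (design@spike_rate > 0) {
    counts <- stats::rpois(n, design@spike_rate)
    for (i in which(counts > 0)) {
      pos <- sample.int(p, counts[i], replace = FALSE)
      out[i, pos] <- out[i, pos] +
        stats::runif(counts[i], design@spike_amplitude_range[1],
                     design@spike_amplitude_range[2])
    }
  }
  out
}

#' Generate one synthetic cell spectrum
#'
#' Draws a single spectrum: polynomial fluorescence baseline plus Lorentzian
#' bands whose amplitudes are scaled by `1 + effect * (multiplier - 1)`,
#' Gaussian noise with standard deviation `noise_scale * sqrt(signal + 1)`,
#' and Poisson-counted single-pixel cosmic-ray spikes. Reproducible under a
#' fixed seed.
#'
#' @param design a [SyntheticDesign-class].
#' @param label class label stored in the spectrum metadata.
#' @param dose_um dose (uM); the fractional effect is [effectFraction()] of it.
#' @param effect optional fractional effect overriding the dose mapping.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a [RamanSpectrum-class].
#' @export
generateSpectrum <- function(design, label = "control", dose_um = 0,
                             effect = NULL, seed = design@seed) {
  validObject(design)
  if (is.null(effect)) effect <- effectFraction(dose_um, design)
  clean <- cleanSignal(design, effect)
  y <- withSeed(seed, addNoiseAndSpikes(design, matrix(clean, 1)))
  RamanSpectrum(design@grid_cm1, drop(y),
                metadata = list(label = label, dose_um = dose_um))
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_group` spectra per condition. In `two_class` mode the
#' conditions are an unstimulated control (dose 0) and a ligand group at
#' `ligand_dose_um`; in `dose_series` mode one group per dose on the design's
#' dose grid, labelled `dose_<x>`. Ganglion mode emulates a population
#' measurement by averaging `k_cells` independent single-cell draws per
#' spectrum, which shrinks the residual noise roughly by 1/sqrt(k).
#'
#' @param design a [SyntheticDesign-class].
#' @param mode `"two_class"` or `"dose_series"`.
#' @param class_labels labels for control and ligand groups (two_class mode).
#' @param ligand_dose_um dose applied to the ligand group (default: top of
#'   the design dose grid).
#' @param ganglion logical; average `k_cells` draws per spectrum.
#' @param k_cells cells averaged per ganglion spectrum.
#' @param seed integer seed (defaults to the design seed).
#' @return a [RamanSet-class] with labels and doses per spectrum.
#' @export
generateDataset <- function(design, mode = c("two_class", "dose_series"),
                            class_labels = c("control", "ligand"),
                            ligand_dose_um = max(design@dose_grid_um),
                            ganglion = FALSE, k_cells = 10L,
                            seed = design@seed) {
  validObject(design)
  mode <- match.arg(mode)
  conditions <- if (mode == "two_class") {
    data.frame(label = class_labels, dose_um = c(0, ligand_dose_um))
  } else {
    data.frame(label = sprintf("dose_%g", design@dose_grid_um),
               dose_um = design@dose_grid_um)
  }
  n <- design@n_per_group
  p <- length(design@grid_cm1)
  withSeed(seed, {
    rows <- vector("list", nrow(conditions))
    for (ci in seq_len(nrow(conditions))) {
      effect <- effectFraction(conditions$dose_um[ci], design)
      clean <- matrix(cleanSignal(design, effect), n, p, byrow = TRUE)
      if (ganglion) {
        acc <- matrix(0, n, p)
        for (k in seq_len(k_cells))
          acc <- acc + addNoiseAndSpikes(design, clean)
        rows[[ci]] <- acc / k_cells
      } else {
        rows[[ci]] <- addNoiseAndSpikes(design, clean)
      }
    }
    RamanSet(design@grid_cm1, do.call(rbind, rows),
             labels = rep(conditions$label, each = n),
             doses_um = rep(conditions$dose_um, each = n),
             metadata = list(design_seed = seed, mode = mode,
                             ganglion = ganglion))
  })
}

#' Generate a synthetic sulfur calibration standard
#'
#' A point-scan sulfur reference with narrow bands at the five standard
#' positions 50.0, 85.1, 153.8, 219.1 and 473.2 cm^-1. A monotone axis
#' distortion may be applied to emulate a miscalibrated instrument: the
#' spectrum is reported on a nominal linear axis while the bands sit at the
#' distorted positions, providing ground truth for calibration round-trips.
#'
#' @param noise_scale additive Gaussian noise standard deviation (a.u.).
#' @param distortion `NULL` (identity) or a monotone function mapping true
#'   wavenumbers to observed positions.
#' @param n_pixels detector pixels of the reported axis.
#' @param range_cm1 reported axis range.
#' @param seed integer seed for the noise.
#' @return list with `spectrum` ([RamanSpectrum-class]), `true_peaks`
#'   and `observed_peaks` (cm^-1).
#' @export
generateSulfurReference <- function(noise_scale = 0, distortion = NULL,
                                    n_pixels = 1024L, range_cm1 = c(40, 500),
                                    seed = 1L) {
  true_peaks <- c(50.0, 85.1, 153.8, 219.1, 473.2)
  amps <- c(1.0, 0.45, 0.85, 0.55, 0.65)
  fwhm <- 2.5
  axis <- seq(range_cm1[1], range_cm1[2], length.out = n_pixels)
  if (is.null(distortion)) {
    observed <- true_peaks
  } else {
    probe <- seq(range_cm1[1], range_cm1[2], length.out = 257L)
    if (any(diff(distortion(probe)) <= 0))
      stop("distortion must be a strictly monotone increasing map")
    observed <- distortion(true_peaks)
  }
  if (any(observed <= min(axis)) || any(observed >= max(axis)))
    stop("distorted peak positions fall outside the reported axis")
  y <- rep(0, n_pixels)
  for (j in seq_along(observed))
    y <- y + amps[j] / (1 + ((axis - observed[j]) / (fwhm / 2))^2)
  if (noise_scale > 0)
    y <- y + withSeed(seed, stats::rnorm(n_pixels, sd = noise_scale))
  list(spectrum = RamanSpectrum(axis, y, metadata = list(label = "sulfur")),
       true_peaks = true_peaks, observed_peaks = observed)
}
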