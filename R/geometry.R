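#' @include AllGenerics.R
NULL

#' Scan geometry of the spiral-scanning Raman microscope
#'
#' Container for the closed-form scan geometry: a circular scan region of
#' diameter D (0.5-100 um), the effective optical path length L from the
#' steering mirror to the specimen, exposure time, and laser marking speed
#' (0.002-2 mm/ms). The mirror deflection angle follows the small-angle
#' relation theta = D / (2 L).
#'
#' @slot diameter_um scan-region diameter D in micrometres.
#' @slot focal_length_m effective path length L in metres.
#' @slot exposure_s exposure time in seconds.
#' @slot marking_speed_mm_per_ms scan speed in mm per millisecond.
#' @export
setClass("ScanGeometry",
         representation(diameter_um = "numeric", focal_length_m = "numeric",
                        exposure_s = "numeric",
                        marking_speed_mm_per_ms = "numeric"))

setValidity("ScanGeometry", function(object) {
  d <- object@diameter_um
  if (d < 0.5 || d > 100) return("diameter_um must lie in [0.5, 100]")
  if (object@focal_length_m <= 0) return("focal_length_m must be positive")
  if (object@exposure_s <= 0) return("exposure_s must be positive")
  s <- object@marking_speed_mm_per_ms
  if (s < 0.002 || s > 2) return("marking speed must lie in [0.002, 2] mm/ms")
  TRUE
})

#' @param diameter_um,focal_length_m,exposure_s,marking_speed_mm_per_ms see slots.
#' @rdname ScanGeometry-class
#' @export
ScanGeometry <- function(diameter_um, focal_length_m,
                         exposure_s = defaultExposure(diameter_um),
                         marking_speed_mm_per_ms = 2) {
  new("ScanGeometry", diameter_um = diameter_um, focal_length_m = focal_length_m,
      exposure_s = exposure_s, marking_speed_mm_per_ms = marking_speed_mm_per_ms)
}

#' Laser beam specification
#'
#' Excitation beam parameters entering the diffraction-limited spot-size
#' formula 2 M^2 lambda / (pi NA): beam propagation factor M, wavelength and
#' objective numerical aperture (at most 1.7, the practical oil-immersion
#' ceiling).
#'
#' @slot beam_quality dimensionless beam propagation factor M.
#' @slot wavelength_nm excitation wavelength in nanometres.
#' @slot numerical_aperture objective NA.
#' @export
setClass("BeamSpec",
         representation(beam_quality = "numeric", wavelength_nm = "numeric",
                        numerical_aperture = "numeric"))

setValidity("BeamSpec", function(object) {
  if (object@beam_quality <= 0) return("beam_quality must be positive")
  if (object@wavelength_nm <= 0) return("wavelength_nm must be positive")
  na <- object@numerical_aperture
  if (na <= 0 || na > 1.7) return("numerical_aperture must lie in (0, 1.7]")
  TRUE
})

#' @param beam_quality,wavelength_nm,numerical_aperture see slots.
#' @rdname BeamSpec-class
#' @export
BeamSpec <- function(beam_quality = 1.1, wavelength_nm = 532,
                     numerical_aperture = 1.3) {
  new("BeamSpec", beam_quality = beam_quality, wavelength_nm = wavelength_nm,
      numerical_aperture = numerical_aperture)
}

#' Default exposure times per scan diameter
#'
#' Bookkeeping defaults pairing scan-region diameters with exposure times
#' (10 um single-cell regions at 3 s, 40 um ganglion regions at 5 s). These
#' are metadata only and never enforced.
#'
#' @param diameter_um optional diameter; when given, returns the matching
#'   exposure (nearest tabulated diameter).
#' @return the table, or a single exposure time in seconds.
#' @export
defaultExposure <- function(diameter_um = NULL) {
  tab <- data.frame(diameter_um = c(10, 40), exposure_s = c(3, 5))
  if (is.null(diameter_um)) return(tab)
  tab$exposure_s[which.min(abs(tab$diameter_um - diameter_um))]
}

#' Galvano-mirror deflection angle
#'
#' Small-angle deflection theta = D / (2 L) for a circular scan region of
#' diameter D at effective path length L, reported in milliradians. Computed
#' in radians internally; the relation is itself the small-angle
#' approximation, so no further validity check is applied.
#'
#' @param object a [ScanGeometry-class], or the diameter in micrometres.
#' @param focal_length_m effective path length L in metres (numeric method).
#' @param ... unused.
#' @return deflection angle in mrad.
#' @export
#' @examples
#' deflectionAngle(10, 0.61)
setMethod("deflectionAngle", "ScanGeometry", function(object, ...)
  deflectionAngle(object@diameter_um, object@focal_length_m))

#' @rdname deflectionAngle-ScanGeometry-method
#' @export
setMethod("deflectionAngle", "numeric", function(object, focal_length_m, ...) {
  diameter_um <- object
  if (any(diameter_um < 0)) stop("diameter must be non-negative")
  if (any(focal_length_m <= 0)) stop("focal length must be positive")
  (diameter_um * 1e-6) / (2 * focal_length_m) * 1e3
})

#' Diffraction-limited laser spot size
#'
#' Spot diameter 2 M^2 lambda / (pi NA); with the wavelength in nanometres
#' the result is in nanometres. The beam propagation factor enters squared.
#'
#' @param object a [BeamSpec-class], or the beam quality M.
#' @param wavelength_nm,numerical_aperture beam parameters (numeric method).
#' @param ... unused.
#' @return spot diameter in nm.
#' @export
#' @examples
#' spotSize(BeamSpec(1.1, 532, 1.3))
setMethod("spotSize", "BeamSpec", function(object, ...)
  spotSize(object@beam_quality, object@wavelength_nm, object@numerical_aperture))

#' @rdname spotSize-BeamSpec-method
#' @export
setMethod("spotSize", "numeric", function(object, wavelength_nm,
                                          numerical_aperture, ...) {
  beam_quality <- object
  if (any(beam_quality <= 0) || any(wavelength_nm <= 0) ||
      any(numerical_aperture <= 0))
    stop("beam parameters must be positive")
  2 * beam_quality^2 * wavelength_nm / (pi * numerical_aperture)
})

#' Infer the effective path length from one measured angle
#'
#' Inverts the small-angle relation: L = D / (2 theta). Round-trips with
#' [deflectionAngle()] to machine precision.
#'
#' @param diameter_um scan diameter in micrometres.
#' @param angle_mrad deflection angle in milliradians.
#' @return effective path length in metres.
#' @export
#' @examples
#' inferFocalLength(10, 0.0082)
inferFocalLength <- function(diameter_um, angle_mrad) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  if (any(angle_mrad <= 0)) stop("angle must be positive")
  (diameter_um * 1e-6) / (2 * angle_mrad * 1e-3)
}

#' Geometry summary table
#'
#' Tabulates deflection angle and diffraction-limited spot size for a set of
#' scan diameters at a fixed path length and beam.
#'
#' @param diameters_um scan diameters in micrometres.
#' @param focal_length_m effective path length in metres.
#' @param beam a [BeamSpec-class].
#' @return `data.frame` with columns `diameter_um`, `theta_mrad`, `spot_nm`.
#' @export
geometryTable <- function(diameters_um, focal_length_m, beam = BeamSpec()) {
  data.frame(diameter_um = diameters_um,
             theta_mrad = deflectionAngle(diameters_um, focal_length_m),
             spot_nm = spotSize(beam))
}
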