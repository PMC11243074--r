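#' Calibrate the wavenumber axis against reference lines
#'
#' Least-squares polynomial of degree `min(2, n_pairs - 1)` mapping observed
#' (instrument-reported) peak positions to true reference wavenumbers. This
#' follows the sulfur-standard protocol: three anchor lines (153.8, 219.1,
#' 473.2 cm^-1) exactly determine the quadratic, so with three pairs the fit
#' interpolates and the residuals vanish; with more pairs the residual RMS
#' is reported. The fitted map must be monotone over the anchor span
#' (expanded by 10%); a non-monotone map signals mismatched peak pairs.
#'
#' @param observed observed peak positions (cm^-1), strictly increasing.
#' @param reference true reference wavenumbers, strictly increasing, same
#'   length.
#' @return a [CalibrationModel-class].
#' @export
#' @examples
#' calibrateWavenumbers(c(153.8, 219.1, 473.2) + 5, c(153.8, 219.1, 473.2))
calibrateWavenumbers <- function(observed, reference) {
  if (length(observed) != length(reference))
    stop("observed and reference must pair up")
  if (length(observed) < 2L)
    stop("calibration needs at least 2 matched peak pairs")
  if (is.unsorted(reference, strictly = TRUE))
    stop("reference peaks must be strictly increasing")
  if (is.unsorted(observed, strictly = TRUE))
    stop("observed peaks must be strictly increasing")
  degree <- min(2L, length(observed) - 1L)
  fit <- stats::lm(reference ~ stats::poly(observed, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  span <- range(observed) + c(-0.1, 0.1) * diff(range(observed))
  deriv <- function(x) {
    v <- 0
    for (k in seq_len(degree)) v <- v + k * coefs[k + 1] * x^(k - 1)
    v
  }
  if (any(deriv(span) <= 0))
    stop("fitted calibration map is non-monotone over the anchor span")
  res <- unname(stats::residuals(fit))
  new("CalibrationModel", coefficients = coefs, degree = degree,
      observed = as.numeric(observed), reference = as.numeric(reference),
      residuals = res, rms = sqrt(mean(res^2)))
}

#' Apply a calibration model
#'
#' Evaluates the calibration polynomial at observed positions, or remaps a
#' spectrum's axis (which must stay strictly increasing).
#'
#' @param model a [CalibrationModel-class].
#' @param x numeric positions or a [RamanSpectrum-class].
#' @return corrected positions, or a recalibrated [RamanSpectrum-class].
#' @export
applyCalibration <- function(model, x) {
  evalPoly <- function(v) {
    out <- 0
    for (k in seq_along(model@coefficients))
      out <- out + model@coefficients[k] * v^(k - 1)
    out
  }
  if (is(x, "RamanSpectrum")) {
    w <- evalPoly(wavenumbers(x))
    if (any(diff(w) <= 0))
      stop("calibrated axis is not strictly increasing over this spectrum")
    RamanSpectrum(w, intensities(x), metadata = x@metadata)
  } else {
    evalPoly(x)
  }
}
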