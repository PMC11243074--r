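#' @include AllGenerics.R
NULL

#' Preprocessing configuration
#'
#' Parameters of the standard chain applied to every spectrum: optional
#' cosmic-ray despiking, Savitzky-Golay smoothing (second polynomial order),
#' iterative order-4 polynomial baseline correction, and cropping plus
#' vector (L2) normalization to the 600-2980 cm^-1 range. The smoothing
#' window defaults to 11 points, narrow enough not to flatten the narrowest
#' cell bands; despiking defaults to off.
#'
#' @slot sg_window odd Savitzky-Golay window length (points).
#' @slot sg_polyorder smoothing polynomial order (default 2).
#' @slot baseline_order baseline polynomial order (default 4).
#' @slot baseline_max_iter iteration cap for the clipped refit.
#' @slot baseline_tol relative convergence tolerance.
#' @slot norm_range_cm1 crop/normalization range, default (600, 2980).
#' @slot despike logical; run the despiker first.
#' @slot despike_z robust z threshold for spike flagging.
#' @slot despike_window running-median window (odd, >= 5).
#' @export
setClass("PreprocessConfig",
         representation(sg_window = "integer", sg_polyorder = "integer",
                        baseline_order = "integer", baseline_max_iter = "integer",
                        baseline_tol = "numeric", norm_range_cm1 = "numeric",
                        despike = "logical", despike_z = "numeric",
                        despike_window = "integer"))

setValidity("PreprocessConfig", function(object) {
  if (object@sg_window %% 2L == 0L) return("sg_window must be odd")
  if (object@sg_window <= object@sg_polyorder)
    return("sg_window must exceed sg_polyorder")
  if (object@sg_polyorder < 0L) return("sg_polyorder must be non-negative")
  if (object@baseline_order < 1L) return("baseline_order must be at least 1")
  if (object@baseline_max_iter < 1L) return("baseline_max_iter must be at least 1")
  if (object@baseline_tol <= 0) return("baseline_tol must be positive")
  if (length(object@norm_range_cm1) != 2L ||
      diff(object@norm_range_cm1) <= 0)
    return("norm_range_cm1 must be an increasing pair")
  if (object@despike_z <= 0) return("despike_z must be positive")
  if (object@despike_window < 5L || object@despike_window %% 2L == 0L)
    return("despike_window must be odd and at least 5")
  TRUE
})

#' @param sg_window,sg_polyorder,baseline_order,baseline_max_iter see slots.
#' @param baseline_tol,norm_range_cm1,despike,despike_z,despike_window see slots.
#' @rdname PreprocessConfig-class
#' @export
preprocessConfig <- function(sg_window = 11L, sg_polyorder = 2L,
                             baseline_order = 4L, baseline_max_iter = 100L,
                             baseline_tol = 1e-4,
                             norm_range_cm1 = c(600, 2980),
                             despike = FALSE, despike_z = 8,
                             despike_window = 5L) {
  new("PreprocessConfig", sg_window = as.integer(sg_window),
      sg_polyorder = as.integer(sg_polyorder),
      baseline_order = as.integer(baseline_order),
      baseline_max_iter = as.integer(baseline_max_iter),
      baseline_tol = baseline_tol, norm_range_cm1 = norm_range_cm1,
      despike = despike, despike_z = despike_z,
      despike_window = as.integer(despike_window))
}

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(paste0("PreprocessConfig: SG window %d order %d; baseline order",
                     " %d; norm %g-%g cm-1; despike %s\n"),
              object@sg_window, object@sg_polyorder, object@baseline_order,
              object@norm_range_cm1[1], object@norm_range_cm1[2],
              if (object@despike) sprintf("z=%.3g", object@despike_z) else "off"))
})

#' Remove single-pixel cosmic-ray spikes
#'
#' Points whose deviation from a running median exceeds `despike_z` robust
#' standard deviations (1.4826 x MAD of the residuals) are replaced by the
#' running median of their neighbours. If more than 5% of points are
#' flagged the spectrum is considered broken and an error is raised rather
#' than silently repaired. The detector assumes shot noise is present; on a
#' noiseless spectrum band shoulders would dominate the residual scale.
#'
#' @param object intensities (numeric) or a [RamanSpectrum-class].
#' @param config a [PreprocessConfig-class].
#' @param ... unused.
#' @return the despiked object, same type as the input.
#' @export
setMethod("despike", "numeric", function(object, config = preprocessConfig(), ...) {
  y <- object
  w <- config@despike_window
  if (length(y) < w) stop("spectrum shorter than the despike window")
  med <- stats::runmed(y, w, endrule = "median")
  resid <- y - med
  s <- 1.4826 * stats::median(abs(resid))
  flag <- abs(resid) > config@despike_z * s
  if (mean(flag) > 0.05)
    stop("despike flagged more than 5% of points; spectrum looks broken")
  y[flag] <- med[flag]
  y
})

#' @rdname despike-numeric-method
#' @export
setMethod("despike", "RamanSpectrum", function(object, config = preprocessConfig(), ...)
  RamanSpectrum(wavenumbers(object),
                despike(intensities(object), config),
                metadata = object@metadata))

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of order `sg_polyorder` over an
#' odd window. Endpoints are handled by fitting the boundary window and
#' evaluating the fit at the edge points, so polynomials up to the chosen
#' order are reproduced exactly everywhere.
#'
#' @param object intensities (numeric) or a [RamanSpectrum-class].
#' @param config a [PreprocessConfig-class].
#' @param ... unused.
#' @return the smoothed object, same type as the input.
#' @export
setMethod("sgSmooth", "numeric", function(object, config = preprocessConfig(), ...) {
  if (config@sg_window > length(object))
    stop("Savitzky-Golay window exceeds the spectrum length")
  signal::sgolayfilt(object, p = config@sg_polyorder, n = config@sg_window)
})

#' @rdname sgSmooth-numeric-method
#' @export
setMethod("sgSmooth", "RamanSpectrum", function(object, config = preprocessConfig(), ...)
  RamanSpectrum(wavenumbers(object), sgSmooth(intensities(object), config),
                metadata = object@metadata))

#' Iterative polynomial baseline correction
#'
#' Modified-polynomial (clipped refit) baseline estimation: fit an order-4
#' polynomial, clip the working spectrum to the fit wherever it exceeds it,
#' and refit until the baseline stops changing (relative tolerance
#' `baseline_tol`) or `baseline_max_iter` is reached. Clipping stops the
#' plain least-squares fit from being pulled up by the Raman bands. On
#' non-convergence the last iterate is returned with a warning rather than
#' an error.
#'
#' @param object intensities (numeric) or a [RamanSpectrum-class].
#' @param x wavenumber axis (numeric method only).
#' @param config a [PreprocessConfig-class].
#' @param ... unused.
#' @return list with `corrected`, `baseline`, `iterations`, `converged`;
#'   for a spectrum input, `corrected` and `baseline` are
#'   [RamanSpectrum-class] objects.
#' @export
setMethod("baselineCorrect", "numeric", function(object, x,
                                                 config = preprocessConfig(), ...) {
  y <- object
  ord <- config@baseline_order
  if (length(y) < ord + 2L)
    stop("baseline correction needs at least baseline_order + 2 points")
  Q <- orthPolyBasis(x, ord)
  scale <- max(abs(y), .Machine$double.eps)
  yw <- y
  fit <- drop(Q %*% crossprod(Q, yw))
  converged <- FALSE
  it <- 1L
  while (it < config@baseline_max_iter) {
    yw <- pmin(yw, fit)
    newfit <- drop(Q %*% crossprod(Q, yw))
    it <- it + 1L
    if (max(abs(newfit - fit)) < config@baseline_tol * scale) {
      fit <- newfit
      converged <- TRUE
      break
    }
    fit <- newfit
  }
  if (!converged && max(abs(y)) > 0)
    warning("baseline refit did not converge in ", config@baseline_max_iter,
            " iterations; returning the last iterate")
  if (max(abs(y)) == 0) converged <- TRUE
  list(corrected = y - fit, baseline = fit, iterations = it,
       converged = converged)
})

#' @rdname baselineCorrect-numeric-method
#' @export
setMethod("baselineCorrect", "RamanSpectrum", function(object,
                                                       config = preprocessConfig(), ...) {
  res <- baselineCorrect(intensities(object), wavenumbers(object), config)
  w <- wavenumbers(object)
  list(corrected = RamanSpectrum(w, res$corrected, metadata = object@metadata),
       baseline = RamanSpectrum(w, res$baseline),
       iterations = res$iterations, converged = res$converged)
})

#' Crop and vector normalize
#'
#' Crops to the normalization range (default 600-2980 cm^-1) and divides by
#' the Euclidean norm over that range, so the output has unit L2 norm and
#' uniform intensity rescaling of the input is removed. Downstream analysis
#' uses only the cropped range.
#'
#' @param object intensities (numeric) or a [RamanSpectrum-class].
#' @param x wavenumber axis (numeric method only).
#' @param config a [PreprocessConfig-class].
#' @param ... unused.
#' @return list `x`, `y` (numeric method) or a cropped unit-norm
#'   [RamanSpectrum-class].
#' @export
setMethod("cropAndVectorNormalize", "numeric", function(object, x,
                                                        config = preprocessConfig(), ...) {
  r <- config@norm_range_cm1
  idx <- which(x >= r[1] & x <= r[2])
  if (length(idx) < 2L)
    stop("normalization range ", r[1], "-", r[2], " cm-1 misses the grid")
  y <- object[idx]
  nrm <- sqrt(sum(y^2))
  if (nrm == 0)
    stop("spectrum is identically zero over the normalization range")
  list(x = x[idx], y = y / nrm)
})

#' @rdname cropAndVectorNormalize-numeric-method
#' @export
setMethod("cropAndVectorNormalize", "RamanSpectrum",
          function(object, config = preprocessConfig(), ...) {
  res <- cropAndVectorNormalize(intensities(object), wavenumbers(object), config)
  RamanSpectrum(res$x, res$y, metadata = object@metadata)
})

#' Full preprocessing pipeline over a spectrum set
#'
#' Applies, per spectrum and in this fixed order: optional despiking,
#' Savitzky-Golay smoothing, iterative polynomial baseline correction, and
#' crop plus vector normalization. Labels and doses are preserved
#' row-for-row; stage errors are annotated with the failing row.
#'
#' @param set a [RamanSet-class] on a shared grid.
#' @param config a [PreprocessConfig-class].
#' @return a [RamanSet-class] on the cropped grid with unit-norm rows.
#' @export
preprocessPipeline <- function(set, config = preprocessConfig()) {
  x <- wavenumbers(set)
  m <- intensityMatrix(set)
  r <- config@norm_range_cm1
  idx <- which(x >= r[1] & x <= r[2])
  if (length(idx) < 2L)
    stop("normalization range misses the shared grid")
  out <- matrix(0, nrow(m), length(idx))
  for (i in seq_len(nrow(m))) {
    out[i, ] <- tryCatch({
      y <- m[i, ]
      if (config@despike) y <- despike(y, config)
      y <- sgSmooth(y, config)
      y <- baselineCorrect(y, x, config)$corrected
      cropAndVectorNormalize(y, x, config)$y
    }, error = function(e)
      stop("preprocessing failed on spectrum ", i, ": ", conditionMessage(e),
           call. = FALSE))
  }
  RamanSet(x[idx], out, labels = spectrumLabels(set),
           doses_um = spectrumDoses(set),
           metadata = c(S4Vectors::metadata(set),
                        list(preprocess = list(
                          sg_window = config@sg_window,
                          sg_polyorder = config@sg_polyorder,
                          baseline_order = config@baseline_order,
                          norm_range_cm1 = config@norm_range_cm1,
                          despike = config@despike))))
}
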