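#' @include AllGenerics.R
NULL

#' Single calibrated Raman spectrum
#'
#' One Raman trace: a strictly increasing wavenumber grid (cm^-1), matched
#' intensities (a.u.) and free-form acquisition metadata (label, dose_um,
#' diameter_um, exposure_s, ...). Spectra shorter than 16 points are rejected
#' as degenerate.
#'
#' @slot wavenumbers numeric, strictly increasing grid in cm^-1.
#' @slot intensities numeric, same length as the grid.
#' @slot metadata list of acquisition metadata.
#' @aliases RamanSpectrum
#' @export
setClass("RamanSpectrum",
         representation(wavenumbers = "numeric", intensities = "numeric",
                        metadata = "list"),
         prototype(metadata = list()))

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers
  y <- object@intensities
  if (length(w) != length(y)) return("wavenumbers and intensities differ in length")
  if (length(w) < 16L) return("a spectrum needs at least 16 points")
  if (any(!is.finite(w))) return("non-finite wavenumbers")
  if (any(diff(w) <= 0)) return("wavenumber grid must be strictly increasing")
  if (any(!is.finite(y))) return("non-finite intensities")
  TRUE
})

#' @param wavenumbers,intensities,metadata see slots.
#' @rdname RamanSpectrum-class
#' @export
RamanSpectrum <- function(wavenumbers, intensities, metadata = list()) {
  new("RamanSpectrum", wavenumbers = as.numeric(wavenumbers),
      intensities = as.numeric(intensities), metadata = metadata)
}

#' @rdname RamanSpectrum-class
#' @param x a `RamanSpectrum`.
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(x) x@wavenumbers)

#' @rdname RamanSpectrum-class
#' @export
setMethod("intensities", "RamanSpectrum", function(x) x@intensities)

#' @rdname RamanSpectrum-class
#' @export
setMethod("length", "RamanSpectrum", function(x) length(x@wavenumbers))

setMethod("show", "RamanSpectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("RamanSpectrum: %d points, %.1f-%.1f cm-1\n",
              length(w), min(w), max(w)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Aligned set of Raman spectra
#'
#' The unit of analysis: an n-spectra x n-points intensity matrix on one
#' shared wavenumber grid with per-spectrum class labels and optional doses.
#' Extends [SummarizedExperiment::SummarizedExperiment] with spectra in
#' columns (Bioconductor sample convention); `intensityMatrix()` returns the
#' spectra-in-rows view used by the chemometrics functions.
#'
#' @aliases RamanSet
#' @export
setClass("RamanSet", contains = "SummarizedExperiment")

setValidity("RamanSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber_cm1" %in% colnames(rd)) return("missing rowData wavenumber_cm1")
  w <- rd$wavenumber_cm1
  if (any(!is.finite(w)) || any(diff(w) <= 0))
    return("wavenumber grid must be finite and strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "dose_um") %in% colnames(cd)))
    return("colData must contain label and dose_um")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(!is.finite(a))) return("non-finite intensities")
  TRUE
})

#' @param wavenumbers shared grid (cm^-1), strictly increasing.
#' @param intensities matrix, one spectrum per row, `length(wavenumbers)` columns.
#' @param labels class label per spectrum (recycled `NA` if omitted).
#' @param doses_um dose per spectrum in micromolar (optional).
#' @param metadata list stored in the object metadata.
#' @rdname RamanSet-class
#' @export
RamanSet <- function(wavenumbers, intensities, labels = NULL, doses_um = NULL,
                     metadata = list()) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity matrix must have one column per wavenumber")
  n <- nrow(intensities)
  labels <- if (is.null(labels)) rep(NA_character_, n) else as.character(labels)
  doses_um <- if (is.null(doses_um)) rep(NA_real_, n) else as.numeric(doses_um)
  if (length(labels) != n) stop("labels length must match the number of spectra")
  if (length(doses_um) != n) stop("doses_um length must match the number of spectra")
  a <- t(unname(intensities))
  colnames(a) <- sprintf("s%d", seq_len(n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = a),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(label = labels, dose_um = doses_um,
                                   row.names = colnames(a)),
    metadata = metadata)
  new("RamanSet", se)
}

#' @rdname RamanSet-class
#' @param x a `RamanSet`.
#' @export
setMethod("wavenumbers", "RamanSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber_cm1)

#' @rdname RamanSet-class
#' @export
setMethod("intensityMatrix", "RamanSet", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname RamanSet-class
#' @export
setMethod("spectrumLabels", "RamanSet", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname RamanSet-class
#' @export
setMethod("spectrumDoses", "RamanSet", function(x)
  SummarizedExperiment::colData(x)$dose_um)

setMethod("show", "RamanSet", function(object) {
  w <- wavenumbers(object)
  cat(sprintf("RamanSet: %d spectra x %d points, %.1f-%.1f cm-1\n",
              ncol(object), length(w), min(w), max(w)))
  lb <- table(spectrumLabels(object), useNA = "no")
  if (length(lb)) cat("  labels:",
                      paste(sprintf("%s (%d)", names(lb), lb), collapse = ", "), "\n")
  d <- spectrumDoses(object)
  if (any(!is.na(d)))
    cat("  doses (uM):", paste(sort(unique(d[!is.na(d)])), collapse = ", "), "\n")
})

#' Extract one spectrum from a RamanSet
#'
#' @param x a [RamanSet-class].
#' @param i spectrum index.
#' @return a [RamanSpectrum-class].
#' @export
getSpectrum <- function(x, i) {
  stopifnot(is(x, "RamanSet"), i >= 1L, i <= ncol(x))
  RamanSpectrum(wavenumbers(x), intensityMatrix(x)[i, ],
                metadata = list(label = spectrumLabels(x)[i],
                                dose_um = spectrumDoses(x)[i]))
}

#' Wavenumber calibration model
#'
#' A degree <= 2 polynomial mapping observed (instrument-reported) peak
#' positions to true wavenumbers, fitted to matched anchor pairs such as the
#' sulfur standard lines. With exactly three anchors the quadratic
#' interpolates and the residuals vanish.
#'
#' @slot coefficients polynomial coefficients, ascending powers.
#' @slot degree fitted degree.
#' @slot observed,reference anchor pairs used for the fit.
#' @slot residuals per-anchor residuals (reference minus fitted).
#' @slot rms residual root-mean-square.
#' @export
setClass("CalibrationModel",
         representation(coefficients = "numeric", degree = "integer",
                        observed = "numeric", reference = "numeric",
                        residuals = "numeric", rms = "numeric"))

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: degree %d, %d anchors, residual RMS %.4g cm-1\n",
              object@degree, length(object@observed), object@rms))
})

#' Principal component model of a spectrum set
#'
#' Column-mean-centred SVD of the intensity matrix with a deterministic sign
#' convention (the largest-magnitude element of each loading is positive).
#'
#' @slot center mean spectrum removed before decomposition.
#' @slot loadings orthonormal loading vectors (points x components).
#' @slot evr explained variance ratio per component, non-increasing.
#' @slot scores training scores (spectra x components).
#' @slot sdev component standard deviations.
#' @slot total_variance total variance of the centred data.
#' @export
setClass("PCAModel",
         representation(center = "numeric", loadings = "matrix",
                        evr = "numeric", scores = "matrix", sdev = "numeric",
                        total_variance = "numeric"))

setValidity("PCAModel", function(object) {
  L <- object@loadings
  if (ncol(L) > 1) {
    g <- crossprod(L)
    if (max(abs(g - diag(ncol(L)))) > 1e-8) return("loadings not orthonormal")
  }
  if (is.unsorted(rev(object@evr))) return("explained variance ratio must be non-increasing")
  if (sum(object@evr) > 1 + 1e-8) return("explained variance ratios sum above 1")
  TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components on %d points\n",
              ncol(object@loadings), nrow(object@loadings)))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", object@evr), collapse = ", "), "\n")
})

#' Binary PLS-DA model
#'
#' NIPALS partial least squares regression of the centred intensity matrix
#' onto a {0, 1} class indicator, used as supervised dimensionality
#' reduction: each spectrum receives `n_components` latent scores.
#'
#' @slot x_center,y_center training means.
#' @slot weights,x_loadings,y_loadings NIPALS weight/loading vectors.
#' @slot projection matrix mapping centred spectra to scores.
#' @slot coefficients regression vector onto the class indicator.
#' @slot scores training scores (spectra x components), mutually orthogonal.
#' @slot classes the two class labels; the second is coded 1.
#' @export
setClass("PLSDAModel",
         representation(x_center = "numeric", y_center = "numeric",
                        weights = "matrix", x_loadings = "matrix",
                        y_loadings = "numeric", projection = "matrix",
                        coefficients = "numeric", scores = "matrix",
                        classes = "character"))

setValidity("PLSDAModel", function(object) {
  Tm <- object@scores
  if (ncol(Tm) > 1) {
    g <- crossprod(Tm)
    nrm <- sqrt(diag(g))
    off <- abs(g / outer(nrm, nrm))
    diag(off) <- 0
    if (max(off, na.rm = TRUE) > 1e-6) return("PLS score vectors not orthogonal")
  }
  if (length(object@classes) != 2L) return("binary model requires two classes")
  TRUE
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d latent components, classes %s (0) vs %s (1)\n",
              ncol(object@scores), object@classes[1], object@classes[2]))
})

#' Mahalanobis nearest-centroid classifier on PLS scores
#'
#' Binomializes multi-dimensional latent scores: class centroids from the
#' training scores, pooled within-class covariance (plus a ridge), and
#' assignment to the class with the smaller Mahalanobis distance.
#'
#' @slot centroids one centroid per row.
#' @slot cov_inv inverse of the ridged pooled covariance.
#' @slot classes class labels matching the centroid rows.
#' @slot ridge ridge added to the covariance diagonal.
#' @export
setClass("MahalanobisClassifier",
         representation(centroids = "matrix", cov_inv = "matrix",
                        classes = "character", ridge = "numeric"))

setValidity("MahalanobisClassifier", function(object) {
  S <- object@cov_inv
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1)) return("covariance inverse not symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("covariance inverse not positive definite")
  TRUE
})

setMethod("show", "MahalanobisClassifier", function(object) {
  cat(sprintf("MahalanobisClassifier: %d-D scores, classes %s; ridge %.3g\n",
              ncol(object@centroids), paste(object@classes, collapse = " vs "),
              object@ridge))
})

#' ROC curve with trapezoidal AUC
#'
#' False-positive vs true-positive rates over a sweep of decision-score
#' thresholds; ties are handled so the AUC equals the normalized rank-sum
#' (Mann-Whitney) statistic.
#'
#' @slot thresholds decision-score thresholds, one per curve vertex.
#' @slot fpr,tpr curve coordinates, non-decreasing from (0,0) to (1,1).
#' @slot auc area under the curve, in [0, 1].
#' @export
setClass("ROCCurve",
         representation(thresholds = "numeric", fpr = "numeric",
                        tpr = "numeric", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    return("fpr/tpr must be non-decreasing")
  if (object@auc < 0 || object@auc > 1) return("auc outside [0, 1]")
  TRUE
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d thresholds, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

#' Calcium fluorescence trace
#'
#' A single-cell calcium indicator time series with its stimulation time;
#' the pre-stimulation frames form the baseline window for delta-F/F.
#'
#' @slot time_s increasing sample times (s).
#' @slot fluorescence_au positive fluorescence values.
#' @slot stim_time_s stimulation onset, strictly inside the record.
#' @slot metadata free-form list (dose, cell id, ...).
#' @export
setClass("CalciumTrace",
         representation(time_s = "numeric", fluorescence_au = "numeric",
                        stim_time_s = "numeric", metadata = "list"),
         prototype(metadata = list()))

setValidity("CalciumTrace", function(object) {
  t <- object@time_s
  f <- object@fluorescence_au
  if (length(t) != length(f)) return("time and fluorescence differ in length")
  if (any(diff(t) <= 0)) return("time must be strictly increasing")
  if (any(!is.finite(f)) || any(f <= 0)) return("fluorescence must be positive and finite")
  s <- object@stim_time_s
  if (s <= min(t) || s > max(t)) return("stim_time_s must lie inside the record")
  if (!any(t < s)) return("empty baseline window")
  TRUE
})

#' @param time_s,fluorescence_au,stim_time_s,metadata see slots.
#' @rdname CalciumTrace-class
#' @export
CalciumTrace <- function(time_s, fluorescence_au, stim_time_s, metadata = list()) {
  new("CalciumTrace", time_s = as.numeric(time_s),
      fluorescence_au = as.numeric(fluorescence_au),
      stim_time_s = as.numeric(stim_time_s), metadata = metadata)
}

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf("CalciumTrace: %d frames over %.1f s, stimulation at %.1f s\n",
              length(object@time_s), max(object@time_s), object@stim_time_s))
})
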