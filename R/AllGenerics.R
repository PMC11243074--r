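#' @name neuroraman-generics
#' @title Generics defined by neuroraman
#' @description Accessor and processing generics used across the package.
#' @param object,x an object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname neuroraman-generics
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname neuroraman-generics
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname neuroraman-generics
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname neuroraman-generics
#' @export
setGeneric("spectrumLabels", function(x) standardGeneric("spectrumLabels"))

#' @rdname neuroraman-generics
#' @export
setGeneric("spectrumDoses", function(x) standardGeneric("spectrumDoses"))

#' @rdname neuroraman-generics
#' @export
setGeneric("deflectionAngle", function(object, ...) standardGeneric("deflectionAngle"))

#' @rdname neuroraman-generics
#' @export
setGeneric("spotSize", function(object, ...) standardGeneric("spotSize"))

#' @rdname neuroraman-generics
#' @export
setGeneric("despike", function(object, ...) standardGeneric("despike"))

#' @rdname neuroraman-generics
#' @export
setGeneric("sgSmooth", function(object, ...) standardGeneric("sgSmooth"))

#' @rdname neuroraman-generics
#' @export
setGeneric("baselineCorrect", function(object, ...) standardGeneric("baselineCorrect"))

#' @rdname neuroraman-generics
#' @export
setGeneric("cropAndVectorNormalize", function(object, ...)
  standardGeneric("cropAndVectorNormalize"))

#' @rdname neuroraman-generics
#' @export
setGeneric("fitPCA", function(object, ...) standardGeneric("fitPCA"))

#' @rdname neuroraman-generics
#' @export
setGeneric("fitPLSDA", function(object, ...) standardGeneric("fitPLSDA"))
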