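#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the previous RNG state so that
#' generator calls are pure functions of their seed and never perturb the
#' caller's random stream. A `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-stage seeds so pipeline
#' stages can be re-run in isolation. The result is a 32-bit-safe positive
#' integer.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
#' @examples
#' stageSeed(1L, "simulate")
stageSeed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(as.numeric(global_seed)) * 100003 + h) %% 2147483629 + 1)
}

# Orthonormal polynomial basis (degree 0..order) on x, as columns of Q.
# x is mapped to [-1, 1] first for conditioning.
orthPolyBasis <- function(x, order) {
  stopifnot(order >= 0L, length(x) >= order + 2L)
  u <- if (diff(range(x)) > 0) 2 * (x - min(x)) / diff(range(x)) - 1 else x * 0
  qr.Q(qr(outer(u, 0:order, `^`)))
}

# Rolling polynomial hash of a character scalar, hex string. Used for config
# fingerprints in run manifests (not cryptographic).
textHash <- function(txt) {
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Detect peaks in a spectrum
#'
#' Local-maximum peak picking with a prominence filter and optional
#' sub-grid apex refinement by a three-point parabola, the standard way to
#' locate narrow calibration lines to better than one grid step.
#'
#' @param x numeric axis (strictly increasing) or a [RamanSpectrum-class].
#' @param y intensities (omit when `x` is a spectrum).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   maximum intensity range; default 0.1.
#' @param refine logical; parabolic apex interpolation (default `TRUE`).
#' @return `data.frame` with columns `position`, `height`, `prominence`,
#'   `index`, ordered by position.
#' @export
detectPeaks <- function(x, y = NULL, min_prominence_frac = 0.1, refine = TRUE) {
  if (is(x, "RamanSpectrum")) {
    y <- intensities(x)
    x <- wavenumbers(x)
  }
  n <- length(y)
  stopifnot(length(x) == n, n >= 3L)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > y[cand - 1L] & y[cand] >= y[cand + 1L]]
  if (!length(cand))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0), index = integer(0)))
  prom <- vapply(cand, function(i) {
    lmin <- y[i]
    j <- i
    while (j > 1L && y[j] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    rmin <- y[i]
    j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence_frac * diff(range(y))
  cand <- cand[keep]
  prom <- prom[keep]
  pos <- x[cand]
  if (refine && length(cand)) {
    for (k in seq_along(cand)) {
      i <- cand[k]
      if (i > 1L && i < n) {
        denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
        if (denom < 0) {
          delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
          step <- (x[i + 1L] - x[i - 1L]) / 2
          pos[k] <- x[i] + delta * step
        }
      }
    }
  }
  ord <- order(pos)
  data.frame(position = pos[ord], height = y[cand][ord],
             prominence = prom[ord], index = cand[ord])
}
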