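#' Read a spectrum from disk
#'
#' Supported formats: plain two-column text (whitespace- or comma-separated,
#' `#` comment lines allowed), two-column CSV with a header row, and the
#' JCAMP-DX `##XYDATA=(X++(Y..Y))` dialect with `XFACTOR`/`YFACTOR` honoured
#' (AFFN numbers only, no SQZ/DIF compression). Descending axes are reversed
#' together with their intensities; the in-memory convention is ascending
#' cm^-1.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"table"`, `"csv"`, `"jcampdx"`; `"auto"`
#'   picks by extension (`.jdx`/`.dx` JCAMP, `.csv` CSV, else table).
#' @return a [RamanSpectrum-class].
#' @export
readSpectrum <- function(path, format = c("auto", "table", "csv", "jcampdx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx")) "jcampdx"
              else if (ext == "csv") "csv" else "table"
  }
  xy <- switch(format,
               table = readXYTable(path, sep = "[,[:space:]]+", header = FALSE),
               csv = readXYTable(path, sep = ",", header = TRUE),
               jcampdx = readJcamp(path))
  if (length(xy$x) < 16L)
    stop("spectrum in '", path, "' has fewer than 16 points")
  if (is.unsorted(xy$x)) {
    if (all(diff(xy$x) < 0)) {
      xy$x <- rev(xy$x)
      xy$y <- rev(xy$y)
    } else stop("axis in '", path, "' is neither ascending nor descending")
  }
  RamanSpectrum(xy$x, xy$y, metadata = list(source = path, format = format))
}

readXYTable <- function(path, sep, header) {
  lines <- readLines(path, warn = FALSE)
  x <- numeric(0)
  y <- numeric(0)
  first_data <- TRUE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, sep)[[1]]
    tok <- tok[nzchar(tok)]
    if (header && first_data && any(is.na(suppressWarnings(as.numeric(tok))))) {
      first_data <- FALSE  # header row
      next
    }
    first_data <- FALSE
    if (length(tok) != 2L)
      stop("line ", i, " of '", path, "': expected 2 columns, found ",
           length(tok))
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("line ", i, " of '", path, "': non-numeric entry '",
           tok[which(is.na(v))[1]], "'")
    x <- c(x, v[1])
    y <- c(y, v[2])
  }
  list(x = x, y = y)
}

readJcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key, default = NA_real_) {
    hit <- grep(sprintf("^##%s=", key), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub("^##[^=]+=\\s*", "", hit[1]))
  }
  xf <- hdr("XFACTOR", 1)
  yf <- hdr("YFACTOR", 1)
  firstx <- hdr("FIRSTX")
  lastx <- hdr("LASTX")
  np <- hdr("NPOINTS")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("'", path, "' has no ##XYDATA=(X++(Y..Y)) block")
  if (any(is.na(c(firstx, lastx, np))))
    stop("'", path, "': FIRSTX, LASTX and NPOINTS are required")
  ys <- numeric(0)
  for (i in (start[1] + 1L):length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) break
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("line ", i, " of '", path, "': non-numeric entry in XYDATA")
    ys <- c(ys, v[-1] * yf)
  }
  if (length(ys) != np)
    stop("'", path, "': NPOINTS = ", np, " but ", length(ys), " Y values read")
  list(x = seq(firstx, lastx, length.out = np), y = ys)
}

#' Write a spectrum to disk
#'
#' Inverse of [readSpectrum()]. Table and CSV output use 17 significant
#' digits so that write-then-read round-trips are bit exact. JCAMP-DX output
#' requires a uniform grid and stores X/Y divided by the chosen factors.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param path output path.
#' @param format `"table"`, `"csv"` or `"jcampdx"`.
#' @param xfactor,yfactor JCAMP-DX scaling factors.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, format = c("table", "csv", "jcampdx"),
                          xfactor = 1, yfactor = 1) {
  format <- match.arg(format)
  x <- wavenumbers(spectrum)
  y <- intensities(spectrum)
  if (format == "table") {
    writeLines(sprintf("%.17g %.17g", x, y), path)
  } else if (format == "csv") {
    writeLines(c("wavenumber_cm1,intensity_au", sprintf("%.17g,%.17g", x, y)),
               path)
  } else {
    d <- diff(x)
    if (max(d) - min(d) > 1e-9 * mean(d))
      stop("JCAMP-DX (X++(Y..Y)) output needs a uniform grid")
    n <- length(x)
    hdr <- c("##TITLE=spectrum", "##JCAMP-DX=4.24", "##DATA TYPE=RAMAN SPECTRUM",
             "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
             sprintf("##XFACTOR=%.17g", xfactor),
             sprintf("##YFACTOR=%.17g", yfactor),
             sprintf("##FIRSTX=%.17g", x[1]), sprintf("##LASTX=%.17g", x[n]),
             sprintf("##NPOINTS=%d", n), "##XYDATA=(X++(Y..Y))")
    body <- character(0)
    i <- 1L
    while (i <= n) {
      j <- min(i + 5L, n)
      body <- c(body, paste(c(sprintf("%.17g", x[i] / xfactor),
                              sprintf("%.17g", y[i:j] / yfactor)),
                            collapse = " "))
      i <- j + 1L
    }
    writeLines(c(hdr, body, "##END="), path)
  }
  invisible(path)
}

#' Read / write a spectrum set as a CSV matrix
#'
#' One spectrum per row; the first two columns are `label` and `dose_um`,
#' the remaining column names are the wavenumbers. Values are stored with 17
#' significant digits so round-trips are lossless.
#'
#' @param path CSV path.
#' @return [readRamanSet()]: a [RamanSet-class].
#' @export
readRamanSet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("label", "dose_um")))
    stop("'", path, "' is not a RamanSet CSV (label, dose_um, <wavenumbers...>)")
  grid <- as.numeric(names(df)[-(1:2)])
  if (any(is.na(grid))) stop("'", path, "': non-numeric wavenumber column names")
  RamanSet(grid, as.matrix(df[, -(1:2), drop = FALSE]),
           labels = df$label, doses_um = df$dose_um)
}

#' @param set a [RamanSet-class].
#' @rdname readRamanSet
#' @export
writeRamanSet <- function(set, path) {
  m <- intensityMatrix(set)
  hdr <- paste(c("label", "dose_um", sprintf("%.17g", wavenumbers(set))),
               collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(spectrumLabels(set)[i], sprintf("%.17g", spectrumDoses(set)[i]),
            sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; values at shared knots are unchanged and
#' extrapolation is refused. Linear interpolation is exact for ramps and,
#' after smoothing, introduces errors well below band heights.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param grid target wavenumber grid inside the source range.
#' @return a [RamanSpectrum-class] on `grid`.
#' @export
resampleToGrid <- function(spectrum, grid) {
  x <- wavenumbers(spectrum)
  if (min(grid) < min(x) || max(grid) > max(x))
    stop("target grid extends beyond the source range; extrapolation refused")
  y <- stats::approx(x, intensities(spectrum), xout = grid)$y
  RamanSpectrum(grid, y, metadata = spectrum@metadata)
}
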