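#' 1D NMR spectrum container
#'
#' A minimal container for a one-dimensional intensity-versus-chemical-shift
#' trace. The ppm axis is stored in ascending order; spectra supplied in the
#' conventional descending NMR order are flipped on construction.
#'
#' @param ppm numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity numeric vector, same length as `ppm`.
#' @param meta optional named list of provenance fields.
#' @return An object of class `nmr_spectrum` with elements `ppm`,
#'   `intensity` and `meta`.
#' @export
nmr_spectrum <- function(ppm, intensity, meta = list()) {
  if (!is.numeric(ppm) || !is.numeric(intensity) ||
      length(ppm) != length(intensity) || length(ppm) < 2L)
    abort("`ppm` and `intensity` must be equal-length numeric vectors (n >= 2)",
          "invalid_parameter")
  d <- diff(ppm)
  if (all(d < 0)) {            # descending convention -> normalize
    ppm <- rev(ppm); intensity <- rev(intensity); d <- -rev(d)
  }
  if (any(d <= 0))
    abort("`ppm` must be strictly monotone", "invalid_parameter")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f..%.3f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Trapezoidal integral of the piecewise-linear interpolant of (ppm, y) over
# [a, b]. Partial end intervals are handled in closed form so that integrals
# over adjacent intervals add exactly: sum over a tiling of [a, b] equals the
# integral over [a, b] to machine precision, which the binning conservation
# invariant relies on.
trap_integral <- function(ppm, y, a, b) {
  n <- length(ppm)
  if (any(a < ppm[1] - 1e-12) || any(b > ppm[n] + 1e-12))
    abort(sprintf("integration range [%g, %g] not covered by ppm axis [%g, %g]",
                  min(a), max(b), ppm[1], ppm[n]), "coverage_error")
  a <- pmax(a, ppm[1]); b <- pmin(b, ppm[n])
  v <- cum_trap_at(ppm, y)(b) - cum_trap_at(ppm, y)(a)
  v[b <= a] <- 0
  v
}

# Closure evaluating the cumulative trapezoidal integral of the
# piecewise-linear interpolant at arbitrary (vectorized) positions.
# Computing the node cumsum once and reusing the closure keeps binning a
# single O(n) pass per spectrum.
cum_trap_at <- function(ppm, y) {
  n <- length(ppm)
  ct <- c(0, cumsum(diff(ppm) * (y[-n] + y[-1]) / 2))
  function(x) {
    i <- findInterval(x, ppm, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    h <- x - ppm[i]
    w <- ppm[i + 1L] - ppm[i]
    yx <- y[i] + (y[i + 1L] - y[i]) * h / w        # linear interpolant
    ct[i] + h * (y[i] + yx) / 2                    # exact partial trapezoid
  }
}

#' Integrate a spectrum over a ppm interval
#'
#' Trapezoidal integral of the piecewise-linear trace over `[a, b]`.
#' @param spectrum an [nmr_spectrum].
#' @param a,b interval bounds in ppm (`a < b`), inside the spectrum's axis.
#' @return The integral (intensity x ppm).
#' @export
spectrum_integral <- function(spectrum, a, b) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  trap_integral(spectrum$ppm, spectrum$intensity, a, b)
}

#' Read a spectrum from a two-column ppm/intensity CSV
#'
#' @param path CSV file with columns `ppm` and `intensity` (header required).
#' @return An [nmr_spectrum].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("ppm", "intensity") %in% names(d)))
    abort(sprintf("%s: expected columns 'ppm' and 'intensity'", path),
          "format_error")
  if (anyNA(d$ppm) || anyNA(d$intensity))
    abort(sprintf("%s: non-numeric or missing cells in spectrum", path),
          "format_error")
  nmr_spectrum(d$ppm, d$intensity, meta = list(source = path))
}

#' Write a spectrum to a two-column CSV
#' @param spectrum an [nmr_spectrum].
#' @param path output file.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a 1D spectrum from a JCAMP-DX file
#'
#' Supports the AFFN `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` forms
#' with a ppm abscissa, which covers files written by [write_spectrum_jdx()]
#' and plain exports from common processing software. Compressed (SQZ/DIF)
#' encodings are not supported.
#'
#' @param path JCAMP-DX file.
#' @return An [nmr_spectrum].
#' @export
read_spectrum_jdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", key, "=\\s*"), "", hit[1], ignore.case = TRUE)
  }
  xy_start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  pt_start <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) end[1] else length(lines) + 1L
  if (length(xy_start)) {
    xf <- as.numeric(get_field("XFACTOR") %||% "1")
    yf <- as.numeric(get_field("YFACTOR") %||% "1")
    dx <- attr_dx(lines, get_field)
    body <- lines[(xy_start[1] + 1L):(end - 1L)]
    body <- body[!grepl("^##", body) & nzchar(trimws(body))]
    vals <- strsplit(trimws(body), "[ \t,]+")
    lens <- lengths(vals)
    if (any(lens < 2L))
      abort(sprintf("%s: unparseable XYDATA line", path), "format_error")
    flat <- as.numeric(unlist(vals, use.names = FALSE))
    if (anyNA(flat))
      abort(sprintf("%s: non-numeric value in XYDATA", path), "format_error")
    first <- cumsum(c(1L, lens[-length(lens)]))      # index of each line's X
    y <- flat[-first] * yf
    x_starts <- flat[first] * xf
    ppm <- x_starts[1] + dx * seq(0, length(y) - 1L)
    # each line's leading X must agree with the reconstructed grid
    at <- cumsum(c(0L, (lens - 1L)[-length(lens)])) + 1L
    if (max(abs(ppm[at] - x_starts)) > 1e-6 * max(abs(dx), 1))
      abort(sprintf("%s: XYDATA line abscissae inconsistent with DELTAX", path),
            "format_error")
    return(nmr_spectrum(ppm, y, meta = list(source = path,
                                            title = get_field("TITLE"))))
  }
  if (length(pt_start)) {
    body <- lines[(pt_start[1] + 1L):(end - 1L)]
    body <- body[!grepl("^##", body) & nzchar(trimws(body))]
    vals <- as.numeric(unlist(strsplit(trimws(body), "[ \t,;]+")))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      abort(sprintf("%s: unparseable XYPOINTS block", path), "format_error")
    idx <- seq(1, length(vals), by = 2)
    return(nmr_spectrum(vals[idx], vals[idx + 1L],
                        meta = list(source = path, title = get_field("TITLE"))))
  }
  abort(sprintf("%s: no ##XYDATA or ##XYPOINTS block found", path),
        "format_error")
}

# X increment for X++(Y..Y): prefer DELTAX, else derive from FIRSTX/LASTX.
attr_dx <- function(lines, get_field) {
  dx <- get_field("DELTAX")
  if (!is.null(dx)) return(as.numeric(dx))
  fx <- as.numeric(get_field("FIRSTX")); lx <- as.numeric(get_field("LASTX"))
  np <- as.numeric(get_field("NPOINTS"))
  if (anyNA(c(fx, lx, np)))
    abort("JCAMP-DX: cannot determine x increment (need DELTAX or FIRSTX/LASTX/NPOINTS)",
          "format_error")
  (lx - fx) / (np - 1)
}

#' Write a 1D spectrum as JCAMP-DX (AFFN XYDATA)
#' @param spectrum an [nmr_spectrum].
#' @param path output file.
#' @param title spectrum title string.
#' @export
write_spectrum_jdx <- function(spectrum, path, title = "pkunmr spectrum") {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ppm <- spectrum$ppm; y <- spectrum$intensity
  dx <- diff(ppm)
  if (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1]))
    abort("JCAMP-DX XYDATA requires an evenly spaced ppm axis", "format_error")
  n <- length(ppm)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", ppm[1]),
    sprintf("##LASTX=%.10g", ppm[n]),
    sprintf("##DELTAX=%.12g", dx[1]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))"), con)
  per_line <- 6L
  for (i in seq(1, n, by = per_line)) {
    j <- min(i + per_line - 1L, n)
    writeLines(paste(c(sprintf("%.10g", ppm[i]),
                       sprintf("%.10g", y[i:j])), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}
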