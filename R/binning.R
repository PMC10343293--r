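#' Spectral binning configuration
#'
#' Defaults follow the standard urinary-NMR bucketing scheme: fixed
#' 0.0088 ppm bins tiling 0.6-9.4 ppm (exactly 1000 bins), with bins
#' touching the residual-water interval 4.5-6.0 ppm discarded, and spectra
#' scaled beforehand to the creatinine CH3 reference integral.
#'
#' @param bin_width bin width, ppm.
#' @param region_start,region_end binned region bounds, ppm.
#' @param exclude_start,exclude_end water exclusion interval (open), ppm;
#'   must lie inside the binned region.
#' @param creatinine_window length-2 ppm interval whose integral is the
#'   creatinine scaling reference (default 3.00-3.12, around the CH3
#'   singlet at 3.05 ppm).
#' @return A `binning_config` object.
#' @export
binning_config <- function(bin_width = 0.0088,
                           region_start = 0.6, region_end = 9.4,
                           exclude_start = 4.5, exclude_end = 6.0,
                           creatinine_window = c(3.00, 3.12)) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (region_start >= region_end)
    abort("region_start must be < region_end", "invalid_parameter")
  if (exclude_start >= exclude_end ||
      exclude_start < region_start || exclude_end > region_end)
    abort("exclusion interval must be an interval inside the binned region",
          "invalid_parameter")
  if (creatinine_window[1] >= creatinine_window[2])
    abort("creatinine_window must be increasing", "invalid_parameter")
  structure(list(bin_width = bin_width, region_start = region_start,
                 region_end = region_end, exclude_start = exclude_start,
                 exclude_end = exclude_end,
                 creatinine_window = creatinine_window),
            class = "binning_config")
}

# Bin edges [left, left + width) tiling the region; the last bin is kept
# only if it fits inside the region (defaults tile it exactly: 1000 bins).
bin_edges <- function(config) {
  n_bins <- floor((config$region_end - config$region_start) /
                    config$bin_width + 1e-9)
  left <- config$region_start + config$bin_width * (seq_len(n_bins) - 1L)
  data.frame(index = seq_len(n_bins), left = left,
             right = left + config$bin_width)
}

retained_bins <- function(config) {
  e <- bin_edges(config)
  # a bin is dropped when its open interval intersects the open water interval
  drop <- e$left < config$exclude_end & e$right > config$exclude_start
  e[!drop, , drop = FALSE]
}

#' Scale a spectrum to its creatinine reference integral
#'
#' Divides every intensity by the trapezoidal integral over the creatinine
#' reference window, making spectra comparable across urine dilutions. The
#' scaled spectrum has reference integral exactly 1.
#'
#' @param spectrum an [nmr_spectrum].
#' @param config a [binning_config].
#' @return The scaled [nmr_spectrum]; the factor applied is stored in
#'   `meta$creatinine_scale`.
#' @export
scale_to_creatinine <- function(spectrum, config = binning_config()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ref <- spectrum_integral(spectrum, config$creatinine_window[1],
                           config$creatinine_window[2])
  if (!is.finite(ref) || ref <= 0)
    abort(sprintf("creatinine reference integral is %g (must be > 0)", ref),
          "degenerate_spectrum")
  out <- spectrum
  out$intensity <- spectrum$intensity / ref
  out$meta$creatinine_scale <- ref
  out
}

#' Bin one spectrum into fixed-width regional integrals
#'
#' Each retained bin value is the trapezoidal integral of the trace over the
#' half-open bin interval. With default settings the region splits into
#' exactly 1000 bins of which 829 survive water exclusion.
#'
#' @param spectrum an [nmr_spectrum] covering the binned region.
#' @param config a [binning_config].
#' @param exclude drop water-region bins (default `TRUE`; `FALSE` returns
#'   all bins, used by conservation checks).
#' @return named numeric vector of bin integrals; names are
#'   `bin<index>` with bin metadata in attribute `edges`.
#' @export
bin_spectrum <- function(spectrum, config = binning_config(), exclude = TRUE) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (spectrum$ppm[1] > config$region_start ||
      spectrum$ppm[length(spectrum$ppm)] < config$region_end)
    abort("spectrum does not cover the binning region", "coverage_error")
  e <- if (exclude) retained_bins(config) else bin_edges(config)
  V <- cum_trap_at(spectrum$ppm, spectrum$intensity)
  vals <- V(e$right) - V(e$left)
  names(vals) <- sprintf("bin%04d", e$index)
  attr(vals, "edges") <- e
  vals
}

#' Assemble a creatinine-scaled bucket table from spectra
#'
#' Applies [scale_to_creatinine()] then [bin_spectrum()] to each spectrum
#' and stacks the rows (samples) by columns (retained bins).
#'
#' @param spectra list of [nmr_spectrum]; differing ppm grids are linearly
#'   interpolated onto the first spectrum's grid (with a message).
#' @param config a [binning_config].
#' @param sample_ids optional row names.
#' @param scale apply creatinine scaling (default `TRUE`).
#' @return A `bucket_table`: list with `matrix` (samples x bins), `edges`
#'   (bin metadata), `scaling` (per-sample reference integrals) and `config`.
#' @export
assemble_bucket_table <- function(spectra, config = binning_config(),
                                  sample_ids = NULL, scale = TRUE) {
  if (!length(spectra)) abort("need at least one spectrum", "invalid_parameter")
  stopifnot(all(vapply(spectra, inherits, TRUE, "nmr_spectrum")))
  ref_ppm <- spectra[[1]]$ppm
  scaling <- numeric(length(spectra))
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (!isTRUE(all.equal(s$ppm, ref_ppm, tolerance = 1e-12))) {
      message(sprintf("spectrum %d interpolated onto the first spectrum's grid", i))
      s <- nmr_spectrum(ref_ppm,
                        stats::approx(s$ppm, s$intensity, xout = ref_ppm,
                                      rule = 2)$y, meta = s$meta)
    }
    res <- tryCatch({
      if (scale) s <- scale_to_creatinine(s, config)
      scaling[i] <- s$meta$creatinine_scale %||% 1
      bin_spectrum(s, config)
    }, pkunmr_error = function(e) {
      abort(sprintf("sample %s: %s",
                    sample_ids[i] %||% as.character(i), conditionMessage(e)),
            class(e)[1])
    })
    rows[[i]] <- res
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sample_ids %||% sprintf("S%03d", seq_along(spectra))
  structure(list(matrix = m, edges = attr(rows[[1]], "edges"),
                 scaling = scaling, config = config),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d bins (%.4g ppm each)\n",
              nrow(x$matrix), ncol(x$matrix), x$config$bin_width))
  invisible(x)
}

#' Write / read a bucket table as CSV
#'
#' The header row carries bin identifiers; bin edge metadata travels in a
#' sidecar header comment line (`# left:...`), so a round trip is lossless.
#' @param bt a `bucket_table`.
#' @param path output path.
#' @export
write_bucket_csv <- function(bt, path) {
  stopifnot(inherits(bt, "bucket_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# bin_width=%.10g region=%.10g:%.10g exclude=%.10g:%.10g",
                     bt$config$bin_width, bt$config$region_start,
                     bt$config$region_end, bt$config$exclude_start,
                     bt$config$exclude_end), con)
  utils::write.csv(data.frame(sample_id = rownames(bt$matrix),
                              bt$matrix, check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bucket_csv
#' @param path CSV written by [write_bucket_csv()].
#' @export
read_bucket_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    abort(sprintf("%s: missing bucket-table header comment", path),
          "format_error")
  field <- function(key, k) {
    m <- regmatches(hdr, regexec(paste0(key, "=([0-9.eE+-]+):?([0-9.eE+-]+)?"),
                                 hdr))[[1]]
    as.numeric(m[k + 1L])
  }
  cfg <- binning_config(bin_width = field("bin_width", 1),
                        region_start = field("region", 1),
                        region_end = field("region", 2),
                        exclude_start = field("exclude", 1),
                        exclude_end = field("exclude", 2))
  d <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  idx <- as.integer(sub("bin", "", colnames(m)))
  e <- bin_edges(cfg)
  structure(list(matrix = m, edges = e[match(idx, e$index), ],
                 scaling = rep(NA_real_, nrow(m)), config = cfg),
            class = "bucket_table")
}
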