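#' Per-voxel fluctuation amplitude map
#'
#' @param values 2D/3D non-negative array.
#' @param kind one of `"RSFA_full"`, `"RSFA_low"`, `"RSFA_high"`,
#'   `"tSD_hc"`, `"tSNR"`.
#' @param band the [filter_band()] used, or `"unfiltered-hc"`.
#' @return object of class `fluctuation_map`.
#' @export
fluctuation_map <- function(values, kind, band = "unfiltered-hc") {
  structure(list(values = values, kind = kind, band = band),
            class = "fluctuation_map")
}

#' @export
print.fluctuation_map <- function(x, ...) {
  cat(sprintf("<fluctuation_map> %s, %s voxels, range %.4g .. %.4g\n",
              x$kind, paste(dim(x$values), collapse = " x "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Extract the voxel array from a fluctuation map
#' @param x a [fluctuation_map()] (or a plain array, returned as is).
#' @return the 2D/3D values array.
#' @export
map_values <- function(x) if (inherits(x, "fluctuation_map")) x$values else x

drop_z <- function(arr, d) {
  if (length(d) >= 3 && d[3] == 1L) dim(arr) <- d[1:2] else dim(arr) <- d[1:3]
  arr
}

#' Resting-state fluctuation amplitude (RSFA)
#'
#' Per-voxel temporal standard deviation of the band-passed series.  The
#' standard bands are full = 0.01-0.15 Hz, low = 0.01-0.1 Hz and
#' high = 0.1-0.15 Hz.  The series should already be detrended (and, if
#' desired, physiologically denoised) — this function only filters and
#' takes the SD.
#'
#' @param ts detrended BOLD [volume_ts()].
#' @param band a [filter_band()] or band name.
#' @param mask optional logical array restricting the computation.
#' @param method filter realization, see [bandpass()].
#' @return a [fluctuation_map()] of kind `RSFA_<band>`.
#' @export
rsfa <- function(ts, band = "full", method = "butterworth", mask = NULL) {
  if (is.character(band)) band <- filter_band(band)
  filt <- bandpass(ts, band, method = method, mask = mask)
  mat <- ts_as_matrix(filt)
  vals <- drop_z(matrixStats_colSds(mat), dim(ts$data))
  fluctuation_map(vals, kind = paste0("RSFA_", band$name), band = band)
}

# column SDs without extra dependencies
matrixStats_colSds <- function(mat) {
  n <- nrow(mat)
  mu <- colMeans(mat)
  sqrt(pmax(colSums(mat^2) / n - mu^2, 0) * n / (n - 1))
}

#' Hypercapnia signal-change amplitude (tSD_hc)
#'
#' Per-voxel temporal standard deviation of the full detrended
#' gas-challenge series (no band-pass; block transitions included).  The
#' paradigm is only used to check that challenge blocks exist.
#'
#' @param ts detrended BOLD [volume_ts()] of the hypercapnia session.
#' @param paradigm the session [paradigm()]; must contain challenge blocks.
#' @return a [fluctuation_map()] of kind `tSD_hc`.
#' @export
tsd_hc <- function(ts, paradigm) {
  stopifnot(inherits(ts, "volume_ts"), inherits(paradigm, "paradigm"))
  if (!has_challenge(paradigm))
    stop("paradigm has no challenge blocks; not a hypercapnia session")
  mat <- ts_as_matrix(ts)
  vals <- drop_z(matrixStats_colSds(mat), dim(ts$data))
  fluctuation_map(vals, kind = "tSD_hc")
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean divided by temporal SD.  Zero-SD voxels are
#' flagged `NaN` with a warning.
#'
#' @param ts a [volume_ts()].
#' @return a [fluctuation_map()] of kind `tSNR`.
#' @export
tsnr <- function(ts) {
  stopifnot(inherits(ts, "volume_ts"))
  mat <- ts_as_matrix(ts)
  s <- matrixStats_colSds(mat)
  m <- colMeans(mat)
  out <- ifelse(s == 0, NaN, m / s)
  if (any(s == 0))
    warning(sum(s == 0), " zero-SD voxels set to NaN")
  fluctuation_map(drop_z(out, dim(ts$data)), kind = "tSNR")
}
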