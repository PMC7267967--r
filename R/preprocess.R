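#' Named frequency band
#'
#' The analysis bands: `full` = 0.01-0.15 Hz, `low` = 0.01-0.1 Hz,
#' `high` = 0.1-0.15 Hz; or an explicit pair of edges.
#'
#' @param name one of `"full"`, `"low"`, `"high"`, or `"custom"`.
#' @param f_lo_hz,f_hi_hz band edges in Hz (required for `"custom"`,
#'   fixed otherwise).
#' @return object of class `filter_band`.
#' @export
filter_band <- function(name = c("full", "low", "high", "custom"),
                        f_lo_hz = NULL, f_hi_hz = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
                  full = c(0.01, 0.15), low = c(0.01, 0.1),
                  high = c(0.1, 0.15), custom = c(f_lo_hz, f_hi_hz))
  if (length(edges) != 2L || !all(is.finite(edges)))
    stop("custom band needs f_lo_hz and f_hi_hz")
  if (!(edges[1] >= 0 && edges[1] < edges[2]))
    stop("need 0 <= f_lo < f_hi")
  structure(list(f_lo_hz = edges[1], f_hi_hz = edges[2], name = name),
            class = "filter_band")
}

# internal: time x voxel matrix view of a series and its inverse
ts_as_matrix <- function(ts) {
  d <- dim(ts$data)
  t(matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_as_ts <- function(mat, template) {
  d <- dim(template$data)
  template$data <- array(t(mat), dim = d)
  template
}

#' Split an interleaved series into VASO and BOLD series
#'
#' Deinterleaves alternating blood-nulled / not-nulled volumes into two
#' series of half length with doubled TR (the effective per-contrast TR)
#' and correct first-volume time offsets.  By convention the nulled
#' (VASO-weighted) volumes come first; set `meta$nulled_first = FALSE` on
#' the input (or `flip = TRUE`) for the opposite order.
#'
#' @param ts interleaved [volume_ts()] with an even number of volumes.
#' @param flip swap the assumed interleaving order.
#' @return list with elements `vaso` and `bold`, both [volume_ts()].
#' @export
split_interleaved <- function(ts, flip = FALSE) {
  stopifnot(inherits(ts, "volume_ts"))
  if (ts$contrast != "interleaved")
    stop("expected an interleaved series, got contrast '", ts$contrast, "'")
  nt <- n_volumes(ts)
  if (nt %% 2L != 0L) stop("odd volume count: cannot split")
  nulled_first <- isTRUE(ts$meta$nulled_first)
  if (flip) nulled_first <- !nulled_first
  odd <- seq(1, nt, by = 2); even <- seq(2, nt, by = 2)
  nulled <- if (nulled_first) odd else even
  notnull <- if (nulled_first) even else odd
  pick <- function(idx, contrast) {
    meta <- ts$meta
    meta$t_offset_s <- ts$meta$t_offset_s + (idx[1] - 1) * ts$tr_s
    meta$nulled_first <- NULL
    volume_ts(ts$data[, , , idx, drop = FALSE], tr_s = 2 * ts$tr_s,
              contrast = contrast, meta = meta)
  }
  list(vaso = pick(nulled, "vaso"), bold = pick(notnull, "bold"))
}

#' Re-interleave VASO and BOLD series
#'
#' Inverse of [split_interleaved()].
#' @param vaso,bold the two half-length series.
#' @param nulled_first interleaving order of the output.
#' @return interleaved [volume_ts()].
#' @export
interleave <- function(vaso, bold, nulled_first = TRUE) {
  stopifnot(n_volumes(vaso) == n_volumes(bold))
  d <- dim(vaso$data)
  arr <- array(0, dim = c(d[1:3], 2L * d[4]))
  nulled <- if (nulled_first) seq(1, 2 * d[4], 2) else seq(2, 2 * d[4], 2)
  notnull <- setdiff(seq_len(2 * d[4]), nulled)
  arr[, , , nulled] <- vaso$data
  arr[, , , notnull] <- bold$data
  t0 <- min(vaso$meta$t_offset_s, bold$meta$t_offset_s)
  volume_ts(arr, tr_s = vaso$tr_s / 2, contrast = "interleaved",
            meta = list(nulled_first = nulled_first, t_offset_s = t0))
}

#' BOLD-correct a VASO series by dynamic division
#'
#' Removes the multiplicative BOLD contamination of the blood-nulled
#' volumes by dividing them, volume by volume, by the paired not-nulled
#' volumes.  Voxels with non-positive not-nulled signal are set to `NaN`
#' and counted in a warning.
#'
#' @param vaso,bold series of equal length and grid from
#'   [split_interleaved()].
#' @return [volume_ts()] with contrast `"vaso_corrected"`.
#' @export
bold_correct_vaso <- function(vaso, bold) {
  stopifnot(inherits(vaso, "volume_ts"), inherits(bold, "volume_ts"))
  if (!all(dim(vaso$data) == dim(bold$data)))
    stop("VASO and BOLD series must share grid and length")
  bad <- bold$data <= 0
  denom <- bold$data
  denom[bad] <- NA_real_
  out <- vaso$data / denom
  out[bad] <- NaN
  if (any(bad))
    warning(sum(bad), " non-positive not-nulled values set to NaN")
  meta <- vaso$meta
  volume_ts(out, tr_s = vaso$tr_s, contrast = "vaso_corrected", meta = meta)
}

#' T1-weighted anatomical reference from an interleaved series
#'
#' Temporal mean of the blood-nulled volumes divided by the temporal mean
#' of the not-nulled volumes.  The signal difference between the two
#' interleaved acquisitions is dominated by longitudinal relaxation, so
#' the ratio yields tissue contrast while cancelling coil sensitivity.
#'
#' @param ts interleaved [volume_ts()].
#' @return 2D/3D array; voxels with zero not-nulled mean are `NaN`.
#' @export
t1w_reference <- function(ts) {
  halves <- split_interleaved(ts)
  num <- apply(halves$vaso$data, 1:3, mean)
  den <- apply(halves$bold$data, 1:3, mean)
  out <- ifelse(den == 0, NaN, num / den)
  if (dim(ts$data)[3] == 1L) dim(out) <- dim(ts$data)[1:2]
  out
}

#' Remove per-voxel linear drift
#'
#' Least-squares line removed voxelwise; the temporal mean is re-added so
#' baseline levels stay meaningful for percent-change computations.
#'
#' @param ts a [volume_ts()] with at least 3 volumes.
#' @return detrended [volume_ts()].
#' @export
linear_detrend <- function(ts) {
  stopifnot(inherits(ts, "volume_ts"))
  nt <- n_volumes(ts)
  if (nt < 3L) stop("need at least 3 volumes to detrend")
  x <- seq_len(nt) - (nt + 1) / 2       # centered time index
  mat <- ts_as_matrix(ts)
  slope <- crossprod(x, mat)[1, ] / sum(x^2)
  mat <- mat - outer(x, slope)          # means untouched (x is centered)
  matrix_as_ts(mat, ts)
}

#' Zero-phase band-pass filter
#'
#' Default realization is a 4th-order Butterworth applied forward and
#' backward (`signal::filtfilt`, zero phase).  `method = "spectral"`
#' applies an ideal transform-domain brick-wall instead (exact band edges,
#' useful for variance-partition checks).
#'
#' @param ts a detrended [volume_ts()].
#' @param band a [filter_band()]; `f_hi_hz` must lie below Nyquist.
#' @param method `"butterworth"` (default) or `"spectral"`.
#' @param mask optional 2D/3D logical array; voxels outside it are passed
#'   through as zeros (saves time on background).
#' @return filtered [volume_ts()] (zero-mean output).
#' @export
bandpass <- function(ts, band, method = c("butterworth", "spectral"),
                     mask = NULL) {
  stopifnot(inherits(ts, "volume_ts"), inherits(band, "filter_band"))
  method <- match.arg(method)
  fs <- 1 / ts$tr_s
  if (band$f_hi_hz >= fs / 2)
    stop(sprintf("band edge %.3g Hz at or above Nyquist %.3g Hz",
                 band$f_hi_hz, fs / 2))
  mat <- ts_as_matrix(ts)
  cols <- if (is.null(mask)) seq_len(ncol(mat)) else which(as.vector(mask))
  out <- matrix(0, nrow(mat), ncol(mat))
  if (method == "spectral") {
    out[, cols] <- spectral_bandpass_mat(mat[, cols, drop = FALSE], fs,
                                         band$f_lo_hz, band$f_hi_hz)
  } else {
    bf <- signal::butter(4, c(band$f_lo_hz, band$f_hi_hz) / (fs / 2),
                         type = "pass")
    sub <- mat[, cols, drop = FALSE]
    sub <- sweep(sub, 2, colMeans(sub))
    out[, cols] <- filtfilt_mat(bf$b, bf$a, sub)
  }
  matrix_as_ts(out, ts)
}

# causal IIR filtering of matrix columns with zero initial conditions
causal_filter_mat <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  x0 <- rbind(matrix(0, nb - 1L, ncol(x)), x)
  u <- stats::filter(x0, b, method = "convolution", sides = 1)
  u <- u[nb:nrow(x0), , drop = FALSE]
  y <- stats::filter(u, -a[-1], method = "recursive")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# forward-backward (zero-phase) filtering of matrix columns; same
# zero-padding convention as signal::filtfilt, vectorized across columns
filtfilt_mat <- function(b, a, x) {
  nt <- nrow(x)
  npad <- 2L * max(length(a), length(b))
  y <- causal_filter_mat(b, a, rbind(x, matrix(0, npad, ncol(x))))
  y <- causal_filter_mat(b, a, y[nrow(y):1, , drop = FALSE])
  y[nrow(y):1, , drop = FALSE][seq_len(nt), , drop = FALSE]
}

# Cardiac phase: linear 0..2pi between successive detected pulse peaks.
cardiac_phase <- function(trace, fs, t_query, min_dist_s = 0.25) {
  n <- length(trace)
  mind <- max(1L, round(min_dist_s * fs))
  is_peak <- logical(n)
  for (k in 2:(n - 1))
    if (trace[k] > trace[k - 1] && trace[k] >= trace[k + 1]) is_peak[k] <- TRUE
  pk <- which(is_peak)
  thr <- stats::quantile(trace, 0.6)
  pk <- pk[trace[pk] > thr]
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) >= mind)]
  if (length(pk) < 3) return(NULL)
  t_pk <- (pk - 1) / fs
  idx <- findInterval(t_query, t_pk)
  ph <- rep(NA_real_, length(t_query))
  ok <- idx >= 1 & idx < length(t_pk)
  ph[ok] <- 2 * pi * (t_query[ok] - t_pk[idx[ok]]) /
    (t_pk[idx[ok] + 1] - t_pk[idx[ok]])
  ph[!ok] <- 2 * pi * ((t_query[!ok] %% (mean(diff(t_pk)))) /
                         mean(diff(t_pk)))
  ph
}

# Respiratory phase: histogram-equalized amplitude, signed by the slope.
respiratory_phase <- function(trace, fs, t_query) {
  sm <- stats::filter(trace, rep(1 / max(1, round(fs / 2)),
                                 max(1, round(fs / 2))), sides = 2)
  sm[is.na(sm)] <- trace[is.na(sm)]
  sm <- as.numeric(sm)
  rng <- range(sm)
  b <- pmax(1L, pmin(100L, 1L + floor(99.99 * (sm - rng[1]) / diff(rng))))
  h <- tabulate(b, 100L)
  cum <- cumsum(h) / sum(h)
  dr <- c(diff(sm), 0)
  ph <- pi * cum[b] * sign(dr)
  idx <- pmax(1L, pmin(length(ph), 1L + round(t_query * fs)))
  ph[idx]
}

#' Physiological noise regression (cardiac/respiratory phase harmonics)
#'
#' Per-voxel least-squares removal of sine and cosine regressors of the
#' cardiac and respiratory phases up to the given harmonic order, with
#' phases assigned at each volume's acquisition time.  If no plausible
#' cardiac peaks can be detected the cardiac terms are skipped with a
#' warning.  The temporal mean is preserved.
#'
#' @param ts a [volume_ts()].
#' @param physio a [physio_trace()] covering the scan duration.
#' @param order harmonic order (default 2).
#' @return corrected [volume_ts()].
#' @export
retroicor <- function(ts, physio, order = 2) {
  stopifnot(inherits(ts, "volume_ts"), inherits(physio, "physio_trace"))
  tvol <- volume_times(ts)
  t_phys <- (length(physio$cardiac) - 1) / physio$fs_hz
  if (max(tvol) > t_phys + 1e-9)
    stop("physiological recording shorter than the scan")
  ph_c <- cardiac_phase(physio$cardiac, physio$fs_hz, tvol)
  ph_r <- respiratory_phase(physio$respiratory, physio$fs_hz, tvol)
  reg <- NULL
  if (is.null(ph_c)) {
    warning("no plausible cardiac peaks detected; skipping cardiac terms")
  } else {
    for (m in seq_len(order))
      reg <- cbind(reg, sin(m * ph_c), cos(m * ph_c))
  }
  for (m in seq_len(order))
    reg <- cbind(reg, sin(m * ph_r), cos(m * ph_r))
  reg <- scale(reg, center = TRUE, scale = FALSE)
  mat <- ts_as_matrix(ts)
  mu <- colMeans(mat)
  qr_reg <- qr(reg)
  resid <- qr.resid(qr_reg, sweep(mat, 2, mu))
  matrix_as_ts(sweep(resid, 2, mu, `+`), ts)
}
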