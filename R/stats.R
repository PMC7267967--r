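#' Per-voxel Z-statistic activation map for a block design
#'
#' Ordinary least-squares fit of `[intercept, response regressor]` per
#' voxel; the regressor is the challenge boxcar passed through the chosen
#' hemodynamic response (exponential vascular response for slow gas
#' challenges, gamma-variate for tasks).  The regressor t-statistic is
#' converted to a Z-score through its null distribution (Student t with
#' `n - 2` degrees of freedom, no autocorrelation correction).  For VASO
#' contrasts the regressor is sign-inverted (a CBV increase lowers the
#' blood-nulled signal), so activation again yields positive Z.
#'
#' Conventional thresholds: Z > 2.3 (p < .01) for BOLD and Z > 1.8
#' (p < .05) for VASO maps.
#'
#' @param ts a detrended [volume_ts()].
#' @param paradigm the block [paradigm()].
#' @param hrf_spec list with `type` (`"exp"` or `"gamma"`) and `tau_s` /
#'   `peak_s`.
#' @param invert sign-invert the regressor; defaults to `TRUE` for
#'   `vaso`/`vaso_corrected` contrasts.
#' @param threshold Z threshold stored with the map (default 2.3, or 1.8
#'   when `invert` is in effect).
#' @return object of class `zstat_map` with `values`, `threshold`,
#'   `design`.
#' @export
glm_zstat <- function(ts, paradigm,
                      hrf_spec = list(type = "exp", tau_s = 30),
                      invert = NULL, threshold = NULL) {
  stopifnot(inherits(ts, "volume_ts"), inherits(paradigm, "paradigm"))
  if (is.null(invert))
    invert <- ts$contrast %in% c("vaso", "vaso_corrected")
  if (is.null(threshold)) threshold <- if (invert) 1.8 else 2.3
  tvol <- volume_times(ts)
  box <- paradigm_boxcar(paradigm, tvol)
  reg <- switch(match.arg(hrf_spec$type, c("exp", "gamma")),
                exp = vascular_response(box, ts$tr_s,
                                        if (is.null(hrf_spec$tau_s)) 30
                                        else hrf_spec$tau_s),
                gamma = gamma_response(box, ts$tr_s,
                                       if (is.null(hrf_spec$peak_s)) 5
                                       else hrf_spec$peak_s))
  if (invert) reg <- -reg
  reg <- reg - mean(reg)
  if (sum(reg^2) < 1e-12 * length(reg))
    stop("design collinear with intercept (no challenge variance)")
  mat <- ts_as_matrix(ts)
  nt <- nrow(mat)
  mat <- sweep(mat, 2, colMeans(mat))
  sxx <- sum(reg^2)
  b <- crossprod(reg, mat)[1, ] / sxx
  rss <- colSums(mat^2) - b^2 * sxx
  df <- nt - 2L
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- ifelse(se == 0, sign(b) * Inf, b / se)
  z <- sign(tval) *
    qnorm(pt(abs(tval), df, lower.tail = FALSE, log.p = TRUE),
          lower.tail = FALSE, log.p = TRUE)
  z[is.infinite(tval)] <- sign(tval[is.infinite(tval)]) * 40
  structure(list(values = drop_z(z, dim(ts$data)), threshold = threshold,
                 design = paradigm, df = df),
            class = "zstat_map")
}

#' @export
print.zstat_map <- function(x, ...) {
  cat(sprintf("<zstat_map> threshold Z > %.2g, max Z = %.3g\n",
              x$threshold, max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Conjunction ROI from BOLD and VASO activation maps
#'
#' GM pixels exceeding both Z thresholds; only the largest 4-connected
#' component is retained.
#'
#' @param zbold,zvaso [glm_zstat()] maps on the same grid.
#' @param gm_mask 2D logical GM mask.
#' @return 2D logical mask.
#' @export
define_roi <- function(zbold, zvaso, gm_mask) {
  stopifnot(inherits(zbold, "zstat_map"), inherits(zvaso, "zstat_map"))
  zb <- zbold$values; zv <- zvaso$values
  if (!all(dim(zb) == dim(zv)) || !all(dim(zb) == dim(gm_mask)))
    stop("maps and mask must share a grid")
  roi <- (zb > zbold$threshold) & (zv > zvaso$threshold) & (gm_mask > 0)
  if (!any(roi))
    stop("empty ROI: no GM pixel exceeds both thresholds. ",
         "Lower the thresholds or check that both contrasts show ",
         "activation in the ribbon.")
  largest_component(roi)
}

#' RSFA-based normalization of a laminar BOLD profile
#'
#' Divides the BOLD profile laminawise by a scaling profile (RSFA or any
#' vascular-amplitude surrogate).  With `rescale = "mean"` the result is
#' multiplied by one constant so its mean equals the input BOLD mean —
#' shape-preserving and unit-comparable, and invariant to rescaling the
#' scale profile by any positive constant.  Non-positive scale values give
#' `NaN` for that lamina with a warning (small denominators make the
#' normalized response unphysically large).
#'
#' @param bold_profile,scale_profile [laminar_profile()]s of equal length.
#' @param rescale `"mean"` (default) or `"none"`.
#' @return a [laminar_profile()].
#' @export
normalize_profile <- function(bold_profile, scale_profile,
                              rescale = c("mean", "none")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(bold_profile, "laminar_profile"),
            inherits(scale_profile, "laminar_profile"))
  if (bold_profile$n_laminae != scale_profile$n_laminae)
    stop("profiles must have the same number of laminae")
  sc <- scale_profile$values
  bad <- !is.finite(sc) | sc <= 0
  if (any(bad)) {
    warning(sum(bad), " laminae with non-positive scale set to NaN")
    sc[bad] <- NA_real_
  }
  v <- bold_profile$values / sc
  if (rescale == "mean") {
    k <- mean(bold_profile$values, na.rm = TRUE) / mean(v, na.rm = TRUE)
    v <- v * k
  }
  v[bad] <- NaN
  laminar_profile(v, depth_fractions = bold_profile$depth_fractions,
                  quantity = paste0(bold_profile$quantity, "/",
                                    scale_profile$quantity))
}

#' RSFA of task residuals
#'
#' Fits the task GLM (see [glm_zstat()]) per voxel, subtracts the fitted
#' response, re-adds the temporal mean, and computes RSFA of the residual
#' series in the given band — the vascular fluctuation amplitude
#' recoverable from a task session without a separate resting scan.
#'
#' @param ts detrended task [volume_ts()].
#' @param paradigm the task [paradigm()].
#' @param band a [filter_band()] or band name.
#' @param hrf_spec as in [glm_zstat()]; gamma-variate by default.
#' @param mask optional logical array restricting the computation.
#' @return a [fluctuation_map()].
#' @export
task_residual_rsfa <- function(ts, paradigm, band = "full",
                               hrf_spec = list(type = "gamma", peak_s = 5),
                               mask = NULL) {
  stopifnot(inherits(ts, "volume_ts"), inherits(paradigm, "paradigm"))
  tvol <- volume_times(ts)
  box <- paradigm_boxcar(paradigm, tvol)
  reg <- switch(match.arg(hrf_spec$type, c("exp", "gamma")),
                exp = vascular_response(box, ts$tr_s,
                                        if (is.null(hrf_spec$tau_s)) 30
                                        else hrf_spec$tau_s),
                gamma = gamma_response(box, ts$tr_s,
                                       if (is.null(hrf_spec$peak_s)) 5
                                       else hrf_spec$peak_s))
  reg <- reg - mean(reg)
  mat <- ts_as_matrix(ts)
  mu <- colMeans(mat)
  mat <- sweep(mat, 2, mu)
  if (sum(reg^2) > 1e-12 * length(reg)) {
    b <- crossprod(reg, mat)[1, ] / sum(reg^2)
    mat <- mat - outer(reg, b)
  }
  resid_ts <- matrix_as_ts(sweep(mat, 2, mu, `+`), ts)
  out <- rsfa(resid_ts, band = band, mask = mask)
  out$kind <- sub("^RSFA", "RSFA_resid", out$kind)
  out
}

#' Ordinary least-squares regression between two laminar profiles
#'
#' Regresses `y` on `x` across laminae (each point one lamina);
#' unweighted.  R-squared is the squared Pearson correlation; the p-value
#' is the two-sided slope test.
#'
#' @param x,y [laminar_profile()]s (or numeric vectors) of equal length
#'   `n >= 3` with finite values.
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
laminar_regression <- function(x, y) {
  xv <- if (inherits(x, "laminar_profile")) x$values else as.numeric(x)
  yv <- if (inherits(y, "laminar_profile")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("profiles must have equal length")
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("need at least 3 laminae with finite values")
  if (var(xv) == 0) stop("zero variance in x")
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> slope %.4g, intercept %.4g, R^2 = %.3f, p = %.2g, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Bland-Altman agreement between two laminar profiles
#'
#' Per-lamina differences against means, with mean difference and
#' limits of agreement at +/- 1.96 SD of the differences.  With
#' `standardize = TRUE` (needed when the two quantities carry different
#' units, e.g. M against RSFA) both profiles are z-scored first.
#'
#' @param x,y [laminar_profile()]s (or numeric vectors) of equal length.
#' @param standardize z-score each profile before differencing.
#' @return list of class `bland_altman_result`: `mean_diff`, `loa_low`,
#'   `loa_high`, `pairs`, plus the per-lamina `means` and `diffs`.
#' @export
bland_altman <- function(x, y, standardize = FALSE) {
  xv <- if (inherits(x, "laminar_profile")) x$values else as.numeric(x)
  yv <- if (inherits(y, "laminar_profile")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("profiles must have equal length")
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (standardize) {
    xv <- (xv - mean(xv)) / sd(xv)
    yv <- (yv - mean(yv)) / sd(yv)
  }
  diffs <- yv - xv
  means <- (xv + yv) / 2
  md <- mean(diffs)
  s <- if (length(diffs) > 1) sd(diffs) else 0
  structure(list(mean_diff = md, loa_low = md - 1.96 * s,
                 loa_high = md + 1.96 * s, pairs = length(diffs),
                 means = means, diffs = diffs),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.4g, limits [%.4g, %.4g], n = %d\n",
    x$mean_diff, x$loa_low, x$loa_high, x$pairs))
  invisible(x)
}
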