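#' Davis-model calibration constants
#'
#' @param alpha_t Grubb exponent coupling total CBV to CBF (default 0.38).
#' @param alpha_v modified Grubb exponent coupling venous CBV to CBF
#'   (default 0.2).
#' @param beta field-dependent exponent coupling R2' to deoxyhemoglobin
#'   (default 1, the high-field approximation).
#' @param te_s echo time in seconds.
#' @return object of class `davis_params`.
#' @export
davis_params <- function(alpha_t = 0.38, alpha_v = 0.2, beta = 1,
                         te_s = 0.024) {
  if (!(alpha_t > 0)) stop("alpha_t must be positive")
  if (!(beta > 0)) stop("beta must be positive")
  if (alpha_v < 0) stop("alpha_v must be non-negative")
  structure(list(alpha_t = alpha_t, alpha_v = alpha_v, beta = beta,
                 te_s = te_s), class = "davis_params")
}

#' @export
print.davis_params <- function(x, ...) {
  cat(sprintf(
    "<davis_params> alpha_t = %.3g, alpha_v = %.3g, beta = %.3g, TE = %g ms\n",
    x$alpha_t, x$alpha_v, x$beta, 1000 * x$te_s))
  invisible(x)
}

#' Davis model, flow form
#'
#' `dS = M * (1 - f^(alpha_t - beta) * r^beta)`, the relative BOLD signal
#' change for normalized CBF `f` and normalized CMRO2 `r`.
#'
#' @param m calibration factor M (maximum relative BOLD signal change).
#' @param f normalized cerebral blood flow CBF/CBF0 (> 0).
#' @param r normalized oxidative metabolic rate CMRO2/CMRO2_0 (> 0).
#' @param params a [davis_params()].
#' @return relative BOLD signal change (dimensionless), vectorized.
#' @export
davis_forward_f <- function(m, f, r = 1, params = davis_params()) {
  if (any(f <= 0) || any(r <= 0)) stop("f and r must be positive")
  m * (1 - f^(params$alpha_t - params$beta) * r^params$beta)
}

#' Modified Davis model, volume form
#'
#' `dS = M * (1 - v_t^(alpha_v - beta/alpha_t) * r^beta)`, replacing the
#' flow dependency by normalized total CBV `v_t = CBV_t / CBV_t0` through
#' Grubb's relationship.
#'
#' @param m calibration factor M.
#' @param v_t normalized total CBV (> 0).
#' @inheritParams davis_forward_f
#' @return relative BOLD signal change, vectorized.
#' @export
davis_forward_v <- function(m, v_t, r = 1, params = davis_params()) {
  if (any(v_t <= 0) || any(r <= 0)) stop("v_t and r must be positive")
  m * (1 - v_t^(params$alpha_v - params$beta / params$alpha_t) *
         r^params$beta)
}

#' Steady-state percent signal change of a block challenge
#'
#' `dS = (S_challenge - S_baseline) / S_baseline` per voxel, where each
#' block contributes only its steady state: the first `settle_s` seconds
#' after every block transition are discarded so the slow vascular
#' transition does not dilute the plateau.
#'
#' @param ts a detrended [volume_ts()].
#' @param paradigm a [paradigm()] with at least one baseline and one
#'   challenge block.
#' @param settle_s seconds trimmed from the start of every block (default
#'   60; must be shorter than the shortest block).
#' @param edge_s seconds trimmed from the end of every block (default two
#'   stored TRs): on interleaved acquisitions the dynamic-division partner
#'   of a block's last volumes lies across the transition.
#' @return per-voxel dS map (2D/3D array, dimensionless).
#' @export
block_percent_change <- function(ts, paradigm, settle_s = 60,
                                 edge_s = 2 * ts$tr_s) {
  stopifnot(inherits(ts, "volume_ts"), inherits(paradigm, "paradigm"))
  blocks <- paradigm$blocks
  if (!has_challenge(paradigm) || !any(blocks$label == "baseline"))
    stop("paradigm needs at least one baseline and one challenge block")
  if (settle_s >= min(blocks$duration_s))
    stop("settle_s must be shorter than the shortest block")
  tvol <- volume_times(ts)
  state <- rep(NA_character_, length(tvol))
  for (i in seq_len(nrow(blocks))) {
    sel <- tvol >= blocks$onset_s[i] + settle_s &
      tvol < blocks$onset_s[i] + blocks$duration_s[i] - edge_s
    state[sel] <- blocks$label[i]
  }
  mat <- ts_as_matrix(ts)
  base <- colMeans(mat[which(state == "baseline"), , drop = FALSE])
  chal <- colMeans(mat[which(state == "challenge"), , drop = FALSE])
  drop_z((chal - base) / base, dim(ts$data))
}

#' Normalized total CBV from a corrected-VASO signal change
#'
#' With blood-nulled signal proportional to `(1 - CBV_t)`, a relative
#' corrected-VASO change `dV` maps to
#' `v_t = 1 - dV * (1 - cbv_t0) / cbv_t0`, where `cbv_t0` is the assumed
#' baseline total CBV fraction of tissue.
#'
#' @param vaso_delta relative corrected-VASO signal change (dimensionless,
#'   negative for a CBV increase).
#' @param cbv_t0 baseline total CBV in ml/ml, in `(0, 0.2]` (default
#'   0.055 for gray matter).
#' @return normalized total CBV `v_t`, vectorized.
#' @export
vt_from_vaso <- function(vaso_delta, cbv_t0 = 0.055) {
  if (any(cbv_t0 <= 0) || any(cbv_t0 > 0.2))
    stop("cbv_t0 must lie in (0, 0.2]")
  v_t <- 1 - vaso_delta * (1 - cbv_t0) / cbv_t0
  if (any(v_t <= 0, na.rm = TRUE))
    stop("non-physical v_t <= 0; check the VASO signal convention")
  v_t
}

#' Calibration factor M from paired hypercapnia responses
#'
#' Inverts the modified Davis model under the isometabolic assumption
#' (`r = 1`): `M = dS_hc / (1 - v_t^(alpha_v - beta/alpha_t))`.  Accepts
#' scalars, vectors, or paired [laminar_profile()]s (in which case
#' first-order error propagation fills the result's `sem` from the input
#' `sem`s).  A `v_t` of exactly 1 gives `NaN` with a warning (zero
#' denominator); negative M values are physically suspect and counted in
#' a warning but returned.
#'
#' @param delta_s_hc relative BOLD change during the challenge (profile or
#'   numeric).
#' @param v_t normalized total CBV during the challenge (profile or
#'   numeric).
#' @param params a [davis_params()].
#' @return same shape as the inputs: numeric or a [laminar_profile()] of
#'   quantity `"M"`.
#' @export
compute_M <- function(delta_s_hc, v_t, params = davis_params()) {
  prof_in <- inherits(delta_s_hc, "laminar_profile")
  ds <- if (prof_in) delta_s_hc$values else delta_s_hc
  vt <- if (inherits(v_t, "laminar_profile")) v_t$values else v_t
  if (length(ds) != length(vt))
    stop("delta_s_hc and v_t must have equal length")
  ex <- params$alpha_v - params$beta / params$alpha_t
  denom <- 1 - vt^ex
  zero <- is.finite(denom) & denom == 0
  if (any(zero)) {
    warning(sum(zero), " laminae with v_t = 1 (zero denominator) set to NaN")
    denom[zero] <- NA_real_
  }
  m <- ds / denom
  m[zero] <- NaN
  if (any(m < 0, na.rm = TRUE))
    warning(sum(m < 0, na.rm = TRUE),
            " negative M values (physically suspect)")
  if (!prof_in) return(m)
  sem <- NULL
  if (!is.null(delta_s_hc$sem) &&
      inherits(v_t, "laminar_profile") && !is.null(v_t$sem)) {
    # first-order (delta-method) propagation:
    # dM/d(dS) = 1/denom;  dM/d(vt) = dS * ex * vt^(ex-1) / denom^2
    dm_ds <- 1 / denom
    dm_dv <- ds * ex * vt^(ex - 1) / denom^2
    sem <- sqrt((dm_ds * delta_s_hc$sem)^2 + (dm_dv * v_t$sem)^2)
  }
  laminar_profile(m, depth_fractions = delta_s_hc$depth_fractions,
                  sem = sem, quantity = "M")
}
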