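#' Hypercapnia-style vascular impulse response
#'
#' First-order (single-exponential rise/fall, time constant `tau_s`)
#' response of the vasculature to a stimulus boxcar, evaluated on a regular
#' time grid.  Plateau value is 1 for a sustained unit stimulus.
#'
#' @param box 0/1 stimulus vector on a grid with spacing `dt_s`.
#' @param dt_s grid spacing in seconds.
#' @param tau_s time constant in seconds (default 30).
#' @return response vector, same length as `box`.
#' @export
vascular_response <- function(box, dt_s, tau_s = 30) {
  a <- 1 - exp(-dt_s / tau_s)
  u <- numeric(length(box))
  prev <- 0
  for (k in seq_along(box)) {
    prev <- prev + a * (box[k] - prev)
    u[k] <- prev
  }
  u
}

#' Gamma-variate hemodynamic response convolution
#'
#' Convolves a stimulus boxcar with a gamma-variate kernel
#' `t^a * exp(-t/b)` peaking at `peak_s` (shape 6), normalized to unit
#' plateau for a sustained stimulus.
#'
#' @inheritParams vascular_response
#' @param peak_s time-to-peak of the kernel in seconds (default 5).
#' @return response vector, same length as `box`.
#' @export
gamma_response <- function(box, dt_s, peak_s = 5) {
  shape <- 6
  scale <- peak_s / shape
  tk <- seq(0, peak_s * 5, by = dt_s)
  h <- tk^shape * exp(-tk / scale)
  h <- h / sum(h)                       # unit plateau
  nh <- length(h)
  x0 <- c(numeric(nh - 1), box)
  y <- stats::filter(x0, h, method = "convolution", sides = 1)
  as.numeric(y[nh:length(x0)])
}

# Ideal (transform-domain) band-pass of the columns of a matrix.
# Frequencies strictly inside [f_lo, f_hi] are kept, everything else
# (including DC) removed.
spectral_bandpass_mat <- function(x, fs, f_lo, f_hi) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                  # two-sided spectrum
  keep <- f >= f_lo & f <= f_hi
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  Re(mvfft(xf, inverse = TRUE)) / n
}

# Common band-limited resting vascular driver, ~unit SD.  Soft-bounded at
# 2.5 SD (vasomotion cannot collapse or burst vessels; unbounded Gaussian
# tails would drive the Davis nonlinearity into non-physical regimes).
rest_driver <- function(n_vols, tr_s, f_lo = 0.01, f_hi = 0.15) {
  w <- rnorm(n_vols)
  w <- spectral_bandpass_mat(matrix(w, ncol = 1), 1 / tr_s, f_lo, f_hi)[, 1]
  2.5 * tanh(w / (2.5 * sd(w)))
}

#' Simulate an interleaved laminar VASO/BOLD session
#'
#' Forward model of one SS-SI-VASO acquisition of the cortical ribbon.
#' Every GM pixel inherits its lamina's ground truth.  The total-CBV
#' timecourse of lamina `i` is
#' `CBV_t(t) = cbv_t0 * (1 + cvr_i * u(t) + cvr_i * rest_amp * w(t))`,
#' where `u(t)` is the paradigm boxcar passed through the vascular response
#' (exponential for a gas challenge, gamma-variate for a task, scaled by
#' `task_gain * neural_i` for tasks) and `w(t)` is one band-limited
#' (0.01-0.15 Hz) stochastic process shared by all laminae — spontaneous
#' fluctuations and evoked responses ride on the same local vascular
#' sensitivity.  BOLD signal changes follow the modified Davis model with
#' the lamina's true M; blood-nulled volumes are proportional to
#' `(1 - CBV_t(t))` times the same BOLD modulation (which the dynamic
#' division correction removes).  Nulled and not-nulled volumes alternate
#' at `tr_s` spacing (nulled first by default).  Additive white thermal
#' noise plus cardiac (~1 Hz) and respiratory (~0.3 Hz) oscillations are
#' superimposed and the oscillations also written to the returned
#' physiological trace.  Pixels outside the ribbon get a WM-like constant
#' baseline (different nulled/not-nulled ratio than GM, giving the
#' T1-weighted reference its tissue contrast).
#'
#' @param gt a [make_ground_truth()] object.
#' @param ribbon a [ribbon_geometry()].
#' @param lamina_map a [grow_equivolume_laminae()] labelling consistent
#'   with `ribbon` (same grid; positive labels exactly on the GM mask).
#' @param paradigm a [paradigm()]; must contain challenge blocks for
#'   `kind = "hypercapnia"` or `"task"` and none for `kind = "rest"`.
#' @param kind session type.
#' @param tr_s volume-to-volume spacing of the interleaved series
#'   (default 0.824 s, i.e. an effective per-contrast TR of 1.648 s).
#' @param physio_fs sampling rate of the physiological trace in Hz.
#' @param duration_s requested session length; defaults to the paradigm
#'   duration and must not exceed it.
#' @param params [davis_params()] used for the forward BOLD model.
#' @param r_challenge normalized CMRO2 during challenge blocks (1 =
#'   isometabolic, the hypercapnia assumption; may exceed 1 for tasks).
#' @param tau_s vascular response time constant for gas challenges.
#' @param seed RNG seed; defaults to `gt$seed`.
#' @param nulled_first interleaving order flag.
#' @return list with elements `ts` (interleaved [volume_ts()]), `physio`
#'   ([physio_trace()]), and `truth` (per-lamina table of the session's
#'   noiseless plateau quantities).
#' @export
simulate_session <- function(gt, ribbon, lamina_map, paradigm,
                             kind = c("hypercapnia", "task", "rest"),
                             tr_s = 0.824, physio_fs = 20,
                             duration_s = NULL, params = NULL,
                             r_challenge = 1, tau_s = 30, seed = NULL,
                             nulled_first = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(gt, "ground_truth"), inherits(ribbon, "ribbon_geometry"),
            inherits(lamina_map, "lamina_map"), inherits(paradigm, "paradigm"))
  if (is.null(params)) params <- davis_params(te_s = gt$te_s, beta = gt$beta)
  if (is.null(seed)) seed <- gt$seed
  if (is.null(duration_s)) duration_s <- paradigm$total_duration_s
  if (duration_s > paradigm$total_duration_s + 1e-9)
    stop("paradigm shorter than requested duration")
  if (kind == "rest" && has_challenge(paradigm))
    stop("kind = 'rest' requires a paradigm without challenge blocks")
  if (kind != "rest" && !has_challenge(paradigm))
    stop("paradigm has no challenge blocks")
  gm <- ribbon$gm_mask
  labels <- lamina_map$labels
  if (!all(dim(labels) == dim(gm)) || !all((labels > 0L) == gm))
    stop("lamina_map inconsistent with ribbon")
  if (lamina_map$n_laminae != gt$n_laminae)
    stop("lamina_map and ground truth disagree on the number of laminae")

  set.seed(seed)
  n_vols <- 2L * floor(duration_s / (2 * tr_s))
  times <- (seq_len(n_vols) - 1) * tr_s
  nlam <- gt$n_laminae

  # challenge drive per lamina: fractional CBV change at unit response
  box <- paradigm_boxcar(paradigm, times)
  if (kind == "hypercapnia") {
    u <- vascular_response(box, tr_s, tau_s)
    drive <- gt$cvr
  } else if (kind == "task") {
    u <- gamma_response(box, tr_s)
    drive <- gt$task_gain * gt$neural * gt$cvr
  } else {
    u <- numeric(n_vols)
    drive <- gt$cvr
  }
  w <- rest_driver(n_vols, tr_s)
  r_t <- 1 + (r_challenge - 1) * u

  # per-lamina normalized total CBV and BOLD change, laminae x volumes
  vt <- 1 + outer(drive, u) + gt$rest_amp * outer(gt$cvr, w)
  ex <- params$alpha_v - params$beta / params$alpha_t
  ds <- gt$m_true * (1 - sweep(vt^ex, 2, r_t^params$beta, `*`))

  # compartment scales (a.u.): GM baseline BOLD signal 100
  s0_gm <- 100; vaso_scale <- 0.55
  s0_wm <- 80; wm_nulled_ratio <- 0.75

  phase_c <- runif(1, 0, 2 * pi); phase_r <- runif(1, 0, 2 * pi)
  f_card <- 1.05; f_resp <- 0.29
  physio_t <- gt$physio_amp * (sin(2 * pi * f_card * times + phase_c) +
                                 sin(2 * pi * f_resp * times + phase_r))

  cbv_t <- sweep(vt, 1, gt$cbv_t0, `*`)
  s_notnull <- s0_gm * (1 + ds)
  s_null <- s0_gm * vaso_scale * (1 - cbv_t) * (1 + ds)
  nulled_idx <- if (nulled_first) seq(1, n_vols, by = 2) else
    seq(2, n_vols, by = 2)
  tc <- s_notnull
  tc[, nulled_idx] <- s_null[, nulled_idx]
  tc <- sweep(tc, 2, 1 + physio_t, `*`)

  bg <- rep(s0_wm, n_vols)
  bg[nulled_idx] <- s0_wm * wm_nulled_ratio
  bg <- bg * (1 + physio_t)

  nx <- nrow(gm); ny <- ncol(gm)
  sig <- matrix(bg, nrow = nx * ny, ncol = n_vols, byrow = TRUE)
  gm_idx <- which(gm)
  sig[gm_idx, ] <- tc[labels[gm_idx], ]
  noise_vox <- rep(mean(gt$noise_sd), nx * ny)
  noise_vox[gm_idx] <- gt$noise_sd[labels[gm_idx]]
  if (any(noise_vox > 0))
    sig <- sig + rnorm(length(sig)) * noise_vox
  arr <- array(sig, dim = c(nx, ny, 1L, n_vols))

  ts <- volume_ts(arr, tr_s = tr_s, contrast = "interleaved",
                  meta = list(kind = kind, seed = seed,
                              nulled_first = nulled_first, t_offset_s = 0))

  np <- max(2L, round(duration_s * physio_fs))
  tp <- (seq_len(np) - 1) / physio_fs
  physio <- physio_trace(
    cardiac = sin(2 * pi * f_card * tp + phase_c) + 0.02 * rnorm(np),
    respiratory = sin(2 * pi * f_resp * tp + phase_r) + 0.02 * rnorm(np),
    fs_hz = physio_fs)

  truth <- data.frame(lamina = seq_len(nlam),
                      depth_fraction = gt$depth_fractions,
                      m_true = gt$m_true, cvr = gt$cvr,
                      drive = drive, cbv_t0 = gt$cbv_t0)
  list(ts = ts, physio = physio, truth = truth)
}
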