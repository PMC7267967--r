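#' Per-lamina ground truth for the session simulator
#'
#' Encodes the physiological quantities the calibration analysis tries to
#' recover.  Lamina 1 is adjacent to the WM border, lamina `n_laminae` to
#' the pial surface.  Baseline venous CBV and cerebrovascular reactivity
#' (CVR) both increase linearly toward the pial surface with a
#' pial-to-WM ratio of `pial_amplification`, reflecting the denser (and
#' draining) venous vasculature near the surface; the true calibration
#' factor is `m_true = kappa * TE * cbv_v0 * dhb0^beta`, so it inherits the
#' same monotone laminar shape.
#'
#' The neural activity profile is flat by default; with `double_peak` it
#' carries two Gaussian bumps (upper and deeper cortical input/output
#' bands), the feature that CBV-weighted VASO resolves but raw BOLD hides
#' under venous amplification.
#'
#' @param n_laminae number of laminae (>= 2), default 15.
#' @param pial_amplification pial/WM ratio (>= 1) of `cbv_v0` and `cvr`.
#' @param double_peak logical; give the neural profile two interior peaks.
#' @param cvr_pial fractional total-CBV response of the pial lamina to a
#'   full-strength vascular challenge (dimensionless; 0.2 means +20% CBV).
#' @param cbv_v0_pial baseline venous CBV of the pial lamina (ml/ml).
#' @param cbv_t0 baseline total CBV (ml/ml), constant across laminae.
#' @param dhb0 baseline deoxyhemoglobin concentration (a.u.).
#' @param te_s echo time in seconds.
#' @param m_pial true M of the pial lamina; fixes the lumped constant
#'   `kappa` via `m_pial = kappa * te_s * cbv_v0_pial * dhb0^beta`.
#' @param beta field-dependent coupling exponent used in `m_true`.
#' @param noise_sd thermal (white) noise SD in signal units (a.u.; the
#'   simulator's baseline BOLD signal is 100 a.u., so 3 gives tSNR ~ 30).
#' @param rest_amp amplitude of spontaneous vascular fluctuations: the
#'   common band-limited resting driver has unit SD and modulates each
#'   lamina's CBV by `cvr * rest_amp`.
#' @param physio_amp relative amplitude of the superimposed cardiac and
#'   respiratory signal oscillations (0 disables them).
#' @param task_gain coupling gain from (neural activity x local CVR) to the
#'   fractional CBV response of a task challenge.
#' @param seed RNG seed stored with the ground truth and used by the
#'   simulator.
#' @return object of class `ground_truth` with per-lamina vectors
#'   `cbv_v0`, `cbv_t0`, `dhb0`, `cvr`, `neural`, `m_true`, `noise_sd`,
#'   scalars `kappa`, `te_s`, `beta`, and `depth_fractions` (lamina
#'   mid-depths, 0 = WM, 1 = pial).
#' @export
make_ground_truth <- function(n_laminae = 15, pial_amplification = 3,
                              double_peak = FALSE, cvr_pial = 0.2,
                              cbv_v0_pial = 0.03, cbv_t0 = 0.055,
                              dhb0 = 1, te_s = 0.024, m_pial = 0.1,
                              beta = 1, noise_sd = 3, rest_amp = 1,
                              physio_amp = 0.004, task_gain = 0.6,
                              seed = 1L) {
  if (n_laminae < 2) stop("need n_laminae >= 2")
  if (pial_amplification < 1) stop("pial_amplification must be >= 1")
  n <- as.integer(n_laminae)
  d <- (seq_len(n) - 0.5) / n           # mid-depth, 0 = WM, 1 = pial
  # linear from 1/amplification (WM lamina) to 1 (pial lamina), so the
  # pial/WM ratio equals pial_amplification exactly
  shape <- seq(1 / pial_amplification, 1, length.out = n)
  cbv_v0 <- cbv_v0_pial * shape
  cvr <- cvr_pial * shape
  neural <- rep(1, n)
  if (double_peak)
    neural <- 1 + 0.2 * exp(-((d - 0.35) / 0.1)^2) +
      0.2 * exp(-((d - 0.8) / 0.1)^2)
  kappa <- m_pial / (te_s * cbv_v0_pial * dhb0^beta)
  m_true <- kappa * te_s * cbv_v0 * dhb0^beta
  structure(list(
    n_laminae = n, depth_fractions = d,
    cbv_v0 = cbv_v0, cbv_t0 = rep(cbv_t0, n), dhb0 = rep(dhb0, n),
    kappa = kappa, te_s = te_s, beta = beta,
    m_true = m_true, cvr = cvr, neural = neural,
    noise_sd = rep(noise_sd, n), rest_amp = rest_amp,
    physio_amp = physio_amp, task_gain = task_gain,
    pial_amplification = pial_amplification, double_peak = double_peak,
    seed = as.integer(seed)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d laminae, pial amplification %.2g, ",
                     "M %.3g (WM) .. %.3g (pial)%s\n"),
              x$n_laminae, x$pial_amplification,
              x$m_true[1], x$m_true[x$n_laminae],
              if (x$double_peak) ", double-peak neural profile" else ""))
  invisible(x)
}

#' Ground truth as a per-lamina table
#' @param x a `ground_truth`.
#' @param ... unused.
#' @return data.frame, one row per lamina.
#' @export
as.data.frame.ground_truth <- function(x, ...) {
  data.frame(lamina = seq_len(x$n_laminae),
             depth_fraction = x$depth_fractions,
             cbv_v0 = x$cbv_v0, cbv_t0 = x$cbv_t0, dhb0 = x$dhb0,
             m_true = x$m_true, cvr = x$cvr, neural = x$neural,
             noise_sd = x$noise_sd)
}

# Per-subject biological variability: independent multiplicative lognormal
# jitter on the reactivity and baseline-venous-CBV profiles.
jitter_ground_truth <- function(gt, sdlog = 0.05, seed = NULL) {
  if (sdlog <= 0) return(gt)
  if (!is.null(seed)) set.seed(seed)
  n <- gt$n_laminae
  gt$cvr <- gt$cvr * exp(rnorm(n, 0, sdlog))
  gt$cbv_v0 <- gt$cbv_v0 * exp(rnorm(n, 0, sdlog))
  gt$m_true <- gt$kappa * gt$te_s * gt$cbv_v0 * gt$dhb0^gt$beta
  gt
}
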