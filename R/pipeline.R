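#' Default pipeline configuration
#'
#' One structured list drives both experiment pipelines; any entry can be
#' overridden via [read_config()] or by editing the list.  Defaults encode
#' the emulated study conditions: 15-min gas-challenge and resting-state
#' sessions at an interleaved volume spacing of 0.824 s (effective
#' per-contrast TR 1.648 s), a quarter-annulus motor-cortex-like ribbon,
#' 15 equivolume laminae, threefold pial-to-WM venous amplification, and
#' thermal noise giving BOLD temporal SNR near 30.
#'
#' @return named list of class `lamcal_config`.
#' @export
lamcal_config <- function() {
  structure(list(
    seed = 1L,
    n_subjects = 9L,            # gas-calibration cohort
    n_subjects_b = 11L,         # task/rest normalization cohort
    n_laminae = 15L,
    pial_amplification = 3,
    grid = c(94L, 94L), r_wm = 56, r_csf = 92, angular_extent = pi / 2,
    tr_s = 0.824,
    rest_duration_s = 900,
    task_duration_s = 1440, task_block_s = 30,
    cvr_pial = 0.2, cbv_v0_pial = 0.03, cbv_t0 = 0.055, m_pial = 0.1,
    noise_sd = 3, rest_amp = 1, physio_amp = 0.004,
    subject_jitter_sdlog = 0.05,
    alpha_t = 0.38, alpha_v = 0.2, beta = 1, te_s = 0.024,
    settle_s = 60, task_settle_s = 10,
    retroicor = FALSE,
    filter_method = "butterworth"
  ), class = c("lamcal_config", "list"))
}

subject_seed <- function(config, s, salt = 0L) {
  as.integer((as.numeric(config$seed) * 10007 + 101 * salt + 13 * s) %%
               2147483647)
}

config_gt <- function(config, double_peak = FALSE, seed = 1L) {
  make_ground_truth(
    n_laminae = config$n_laminae,
    pial_amplification = config$pial_amplification,
    double_peak = double_peak,
    cvr_pial = config$cvr_pial, cbv_v0_pial = config$cbv_v0_pial,
    cbv_t0 = config$cbv_t0, te_s = config$te_s, m_pial = config$m_pial,
    beta = config$beta, noise_sd = config$noise_sd,
    rest_amp = config$rest_amp, physio_amp = config$physio_amp,
    seed = seed)
}

config_ribbon <- function(config) {
  make_ribbon(config$r_wm, config$r_csf, config$angular_extent,
              grid_shape = config$grid)
}

config_params <- function(config) {
  davis_params(alpha_t = config$alpha_t, alpha_v = config$alpha_v,
               beta = config$beta, te_s = config$te_s)
}

# split + optional physiological denoising + BOLD correction + detrend
prepare_session <- function(sim, config) {
  halves <- split_interleaved(sim$ts)
  if (isTRUE(config$retroicor)) {
    halves$bold <- retroicor(halves$bold, sim$physio)
    halves$vaso <- retroicor(halves$vaso, sim$physio)
  }
  vaso_corr <- bold_correct_vaso(halves$vaso, halves$bold)
  list(bold = linear_detrend(halves$bold),
       vaso_corr = linear_detrend(vaso_corr))
}

#' Gas-calibration experiment: RSFA against tSD_hc and M
#'
#' For each simulated subject: one 15-min hypercapnia and one 15-min
#' resting-state interleaved session are generated from per-subject
#' jittered ground truth, split, BOLD-corrected and detrended; laminar
#' profiles of RSFA (full/low/high band), tSD_hc, the hypercapnia BOLD
#' response, the corrected-VASO-derived normalized CBV, and the inverted
#' calibration factor M are extracted; and six per-subject laminar
#' regressions (each RSFA band against tSD_hc and against M) plus
#' Bland-Altman statistics are computed.  Group mean and SD of R-squared
#' per pair and band are aggregated across subjects.
#'
#' @param config a [lamcal_config()] list.
#' @return object of class `experiment_report` with per-subject profiles
#'   and truth tables, the long regression table, group summary, and
#'   Bland-Altman results.
#' @export
run_experiment_a <- function(config = lamcal_config()) {
  ribbon <- config_ribbon(config)
  lmap <- grow_equivolume_laminae(ribbon, config$n_laminae)
  params <- config_params(config)
  paradigm_hc <- hypercapnia_paradigm()
  paradigm_rs <- rest_paradigm(config$rest_duration_s)
  bands <- c("full", "low", "high")

  subjects <- vector("list", config$n_subjects)
  rows <- list(); ba <- list()
  for (s in seq_len(config$n_subjects)) {
    gt_s <- jitter_ground_truth(config_gt(config, seed = subject_seed(config, s)),
                                sdlog = config$subject_jitter_sdlog,
                                seed = subject_seed(config, s, salt = 1L))
    sim_hc <- simulate_session(gt_s, ribbon, lmap, paradigm_hc,
                               kind = "hypercapnia", tr_s = config$tr_s,
                               seed = subject_seed(config, s, salt = 2L))
    sim_rs <- simulate_session(gt_s, ribbon, lmap, paradigm_rs,
                               kind = "rest", tr_s = config$tr_s,
                               seed = subject_seed(config, s, salt = 3L))
    hc <- prepare_session(sim_hc, config)
    rs <- prepare_session(sim_rs, config)
    gm <- ribbon$gm_mask

    prof <- list()
    prof$tSD_hc <- extract_profile(map_values(tsd_hc(hc$bold, paradigm_hc)),
                                   lmap, "tSD_hc")
    for (b in bands)
      prof[[paste0("RSFA_", b)]] <- extract_profile(
        map_values(rsfa(rs$bold, b, method = config$filter_method,
                        mask = gm)), lmap, paste0("RSFA_", b))
    prof$dS_hc <- extract_profile(
      block_percent_change(hc$bold, paradigm_hc, config$settle_s),
      lmap, "dS_hc")
    prof$vaso_delta <- extract_profile(
      block_percent_change(hc$vaso_corr, paradigm_hc, config$settle_s),
      lmap, "vaso_delta")
    vt <- laminar_profile(vt_from_vaso(prof$vaso_delta$values, config$cbv_t0),
                          depth_fractions = lmap$depth_fractions,
                          sem = prof$vaso_delta$sem *
                            (1 - config$cbv_t0) / config$cbv_t0,
                          quantity = "v_t")
    prof$v_t <- vt
    prof$M <- compute_M(prof$dS_hc, vt, params)
    prof$tSNR_bold <- extract_profile(map_values(tsnr(hc$bold)), lmap,
                                      "tSNR_bold")
    prof$tSNR_vaso <- extract_profile(
      map_values(suppressWarnings(tsnr(split_interleaved(sim_hc$ts)$vaso))),
      lmap, "tSNR_vaso")

    for (pair in c("tSD_hc", "M")) for (b in bands) {
      reg <- laminar_regression(prof[[paste0("RSFA_", b)]], prof[[pair]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, pair = pair, band = b, slope = reg$slope,
        intercept = reg$intercept, r_squared = reg$r_squared,
        p_value = reg$p_value, n = reg$n)
      ba[[length(ba) + 1L]] <- c(
        list(subject = s, pair = pair, band = b),
        bland_altman(prof[[paste0("RSFA_", b)]], prof[[pair]],
                     standardize = TRUE)[c("mean_diff", "loa_low",
                                           "loa_high", "pairs")])
    }
    subjects[[s]] <- list(profiles = prof,
                          truth = as.data.frame(gt_s))
  }
  regression_table <- do.call(rbind, rows)
  group_summary <- stats::aggregate(
    r_squared ~ pair + band, data = regression_table,
    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  group_summary <- data.frame(group_summary[1:2],
                              r2_mean = group_summary$r_squared[, "mean"],
                              r2_sd = group_summary$r_squared[, "sd"])
  structure(list(experiment = "a", subjects = subjects,
                 regression_table = regression_table,
                 bland_altman = do.call(rbind, lapply(ba, as.data.frame)),
                 group_summary = group_summary,
                 config = config, seed = config$seed),
            class = "experiment_report")
}

group_mean_profile <- function(subjects, name) {
  mats <- vapply(subjects, function(s) s$profiles[[name]]$values,
                 numeric(subjects[[1]]$profiles[[name]]$n_laminae))
  laminar_profile(rowMeans(as.matrix(mats)),
                  depth_fractions = subjects[[1]]$profiles[[name]]$depth_fractions,
                  quantity = name)
}

#' Task/rest experiment: RSFA-normalized BOLD against VASO profiles
#'
#' For each simulated subject (double-peaked neural activity profile): one
#' task and one resting-state interleaved session are generated; laminar
#' profiles of the task BOLD and corrected-VASO percent signal changes are
#' extracted alongside RSFA profiles from the resting scan and from the
#' task residuals, and the BOLD profile is normalized by both RSFA
#' profiles.  Group mean profiles and the peak-location comparison against
#' the VASO (CBV) profile are reported.
#'
#' @param config a [lamcal_config()] list.
#' @return object of class `experiment_report` with per-subject and group
#'   mean profiles plus the peak analysis.
#' @export
run_experiment_b <- function(config = lamcal_config()) {
  ribbon <- config_ribbon(config)
  lmap <- grow_equivolume_laminae(ribbon, config$n_laminae)
  paradigm_task <- task_paradigm(config$task_duration_s, config$task_block_s)
  paradigm_rs <- rest_paradigm(config$task_duration_s)
  hrf <- list(type = "gamma", peak_s = 5)

  subjects <- vector("list", config$n_subjects_b)
  for (s in seq_len(config$n_subjects_b)) {
    gt_s <- jitter_ground_truth(
      config_gt(config, double_peak = TRUE,
                seed = subject_seed(config, s, salt = 10L)),
      sdlog = config$subject_jitter_sdlog,
      seed = subject_seed(config, s, salt = 11L))
    sim_task <- simulate_session(gt_s, ribbon, lmap, paradigm_task,
                                 kind = "task", tr_s = config$tr_s,
                                 seed = subject_seed(config, s, salt = 12L))
    sim_rs <- simulate_session(gt_s, ribbon, lmap, paradigm_rs,
                               kind = "rest", tr_s = config$tr_s,
                               seed = subject_seed(config, s, salt = 13L))
    task <- prepare_session(sim_task, config)
    rs <- prepare_session(sim_rs, config)
    gm <- ribbon$gm_mask

    prof <- list()
    prof$dS_bold <- extract_profile(
      block_percent_change(task$bold, paradigm_task, config$task_settle_s),
      lmap, "dS_bold")
    vaso_ds <- block_percent_change(task$vaso_corr, paradigm_task,
                                    config$task_settle_s)
    # CBV-weighted response: sign-flip so a CBV increase plots positive
    prof$dS_vaso <- extract_profile(-vaso_ds, lmap, "dS_vaso")
    prof$RSFA_rest <- extract_profile(
      map_values(rsfa(rs$bold, "full", method = config$filter_method,
                      mask = gm)), lmap, "RSFA_rest")
    prof$RSFA_resid <- extract_profile(
      map_values(task_residual_rsfa(task$bold, paradigm_task, "full",
                                    hrf_spec = hrf, mask = gm)),
      lmap, "RSFA_resid")
    prof$bold_norm_rest <- normalize_profile(prof$dS_bold, prof$RSFA_rest)
    prof$bold_norm_resid <- normalize_profile(prof$dS_bold, prof$RSFA_resid)
    subjects[[s]] <- list(profiles = prof, truth = as.data.frame(gt_s))
  }
  nm <- names(subjects[[1]]$profiles)
  group_profiles <- lapply(stats::setNames(nm, nm),
                           function(p) group_mean_profile(subjects, p))
  peaks <- list(
    vaso = profile_peaks(group_profiles$dS_vaso),
    bold_raw = profile_peaks(group_profiles$dS_bold),
    bold_norm_rest = profile_peaks(group_profiles$bold_norm_rest),
    bold_norm_resid = profile_peaks(group_profiles$bold_norm_resid))
  structure(list(experiment = "b", subjects = subjects,
                 group_profiles = group_profiles, peaks = peaks,
                 config = config, seed = config$seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> experiment %s, %d subjects\n",
              toupper(x$experiment), length(x$subjects)))
  if (x$experiment == "a") {
    cat("Group R^2 (mean +/- SD across subjects):\n")
    gs <- x$group_summary
    for (i in seq_len(nrow(gs)))
      cat(sprintf("  %s vs RSFA_%s: %.2f +/- %.2f\n",
                  gs$pair[i], gs$band[i], gs$r2_mean[i], gs$r2_sd[i]))
  } else {
    cat("Group profile peaks (lamina indices, 1 = WM):\n")
    for (nm in names(x$peaks))
      cat(sprintf("  %s: %s\n", nm,
                  if (length(x$peaks[[nm]]))
                    paste(x$peaks[[nm]], collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Stores per-subject profile tables, the regression/Bland-Altman tables
#' (experiment A) or group profiles and peaks (experiment B), and the
#' configuration, so a report round-trips through [read_report()].
#'
#' @param report an `experiment_report`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- list(experiment = report$experiment, seed = report$seed,
              config = report$config[setdiff(names(report$config), NULL)],
              subjects = lapply(report$subjects, function(s)
                list(profiles = lapply(s$profiles, as.data.frame),
                     truth = s$truth)))
  if (report$experiment == "a") {
    ser$regression_table <- report$regression_table
    ser$bland_altman <- report$bland_altman
    ser$group_summary <- report$group_summary
  } else {
    ser$group_profiles <- lapply(report$group_profiles, as.data.frame)
    ser$peaks <- report$peaks
  }
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a serialized experiment report
#'
#' @param path `.json` written by [write_report()].
#' @return list mirroring the report structure (tables as data.frames).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
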