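test_that("Davis flow form: baseline identity, worked value, monotonicity", {
  expect_equal(davis_forward_f(0.08, 1, 1), 0)
  # brute-force evaluation written out in full, independent of the package
  expect_equal(davis_forward_f(0.08, 1.5, 1),
               0.08 * (1 - 1.5^(0.38 - 1) * 1^1), tolerance = 1e-12)
  expect_equal(davis_forward_f(0.08, 1.5, 1), 0.01778, tolerance = 1e-3)
  # dS decreases without bound as r grows at fixed f
  r <- c(1, 2, 5, 20)
  expect_true(all(diff(davis_forward_f(0.08, 1.5, r)) < 0))
  expect_error(davis_forward_f(0.08, -1, 1), "positive")
})

test_that("Davis volume form: baseline identity, worked value, monotonicity", {
  expect_equal(davis_forward_v(0.0559, 1, 1), 0)
  expect_equal(davis_forward_v(0.0559, 1.2, 1),
               0.0559 * (1 - 1.2^(0.2 - 1 / 0.38)), tolerance = 1e-12)
  expect_equal(davis_forward_v(0.0559, 1.2, 1), 0.0200, tolerance = 2e-3)
  v <- seq(1, 1.6, by = 0.1)
  expect_true(all(diff(davis_forward_v(0.08, v, 1)) > 0))
})

test_that("M inversion: trivial zero, worked value, inverse identity", {
  expect_equal(compute_M(0, 1.2), 0)
  expect_equal(compute_M(0.02, 1.2), 0.0559, tolerance = 2e-3)
  for (m in c(0.01, 0.08, 0.3)) for (v in c(1.05, 1.2, 1.6))
    expect_equal(compute_M(davis_forward_v(m, v, 1), v), m,
                 tolerance = 1e-12)
  expect_warning(bad <- compute_M(0.02, 1), "zero denominator")
  expect_true(is.nan(bad))
  expect_warning(compute_M(-0.02, 1.2), "negative M")
})

test_that("M inversion on profiles propagates SEM by the delta method", {
  ds <- laminar_profile(c(0.01, 0.02), sem = c(0.001, 0.001),
                        quantity = "dS_hc")
  vt <- laminar_profile(c(1.1, 1.2), sem = c(0.01, 0.01), quantity = "v_t")
  m <- compute_M(ds, vt)
  expect_s3_class(m, "laminar_profile")
  expect_equal(m$quantity, "M")
  # numerical derivative cross-check of the propagated SEM
  eps <- 1e-6
  d_ds <- (compute_M(0.01 + eps, 1.1) - compute_M(0.01, 1.1)) / eps
  d_vt <- (compute_M(0.01, 1.1 + eps) - compute_M(0.01, 1.1)) / eps
  expect_equal(m$sem[1], sqrt((d_ds * 0.001)^2 + (d_vt * 0.01)^2),
               tolerance = 1e-4)
})

test_that("block percent change is the steady-state contrast", {
  p <- mini_hc_paradigm()
  tt <- seq(0, 419, by = 1)
  x <- ifelse(paradigm_boxcar(p, tt) == 1, 102, 100)
  ts <- ts_from_matrix(rbind(x), tr_s = 1)
  expect_equal(as.numeric(block_percent_change(ts, p, settle_s = 20)), 0.02,
               tolerance = 1e-9)
  expect_equal(as.numeric(block_percent_change(constant_ts(7, 420, tr_s = 1),
                                               p, settle_s = 20)), 0)
  expect_error(block_percent_change(ts, p, settle_s = 60), "shorter")
})

test_that("exponential transitions are trimmed to within 1% of the plateau", {
  p <- hypercapnia_paradigm()
  tt <- seq(0, 899, by = 1.648)
  u <- vascular_response(paradigm_boxcar(p, tt), 1.648, tau_s = 30)
  x <- 100 * (1 + 0.02 * u)
  ts <- ts_from_matrix(rbind(x), tr_s = 1.648)
  ds <- as.numeric(block_percent_change(ts, p, settle_s = 60))
  expect_equal(ds, 0.02, tolerance = 0.08)   # block means, not plateau
  # with near-instant transitions the contrast equals the plateau exactly
  u2 <- vascular_response(paradigm_boxcar(p, tt), 1.648, tau_s = 2)
  ts2 <- ts_from_matrix(rbind(100 * (1 + 0.02 * u2)), tr_s = 1.648)
  expect_equal(as.numeric(block_percent_change(ts2, p, settle_s = 60)), 0.02,
               tolerance = 1e-4)
})

test_that("VASO conversion follows the nulled-signal convention", {
  expect_equal(vt_from_vaso(0), 1)
  expect_equal(vt_from_vaso(-0.02, 0.055), 1 + 0.02 * 0.945 / 0.055,
               tolerance = 1e-12)
  expect_equal(vt_from_vaso(-0.02, 0.055), 1.3436, tolerance = 1e-4)
  expect_error(vt_from_vaso(0, cbv_t0 = 0.5), "0, 0.2")
  expect_error(vt_from_vaso(0.2, 0.055), "non-physical")
})

test_that("VASO conversion round-trips the simulator's forward convention", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  gt <- small_gt()
  sim <- simulate_session(gt, rib, lmap, hypercapnia_paradigm(),
                          "hypercapnia", tau_s = 2)
  halves <- split_interleaved(sim$ts)
  corr <- bold_correct_vaso(halves$vaso, halves$bold)
  vd <- extract_profile(block_percent_change(corr, hypercapnia_paradigm()),
                        lmap)
  vt <- vt_from_vaso(vd$values, cbv_t0 = gt$cbv_t0[1])
  expect_equal(vt, 1 + gt$cvr, tolerance = 1e-4)
})

test_that("exponent variations rescale M but preserve the laminar shape", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  gt <- small_gt()
  sim <- simulate_session(gt, rib, lmap, hypercapnia_paradigm(),
                          "hypercapnia", tau_s = 5)
  halves <- split_interleaved(sim$ts)
  corr <- bold_correct_vaso(halves$vaso, halves$bold)
  ds <- extract_profile(block_percent_change(halves$bold,
                                             hypercapnia_paradigm()), lmap)
  vd <- extract_profile(block_percent_change(corr, hypercapnia_paradigm()),
                        lmap)
  vt <- vt_from_vaso(vd$values, gt$cbv_t0[1])
  ref_rank <- rank(gt$m_true)
  for (av in c(0.1, 0.2, 0.3)) for (be in c(0.9, 1.2, 1.5)) {
    m <- compute_M(ds$values, vt, davis_params(alpha_v = av, beta = be))
    expect_equal(rank(m), ref_rank)
  }
})

test_that("pure-BOLD modulation with constant CBV divides out completely", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  gt <- small_gt(cvr_pial = 1e-9, rest_amp = 0)
  sim <- simulate_session(gt, rib, lmap, hypercapnia_paradigm(),
                          "hypercapnia", r_challenge = 1.3)
  halves <- split_interleaved(sim$ts)
  rel_sd <- function(ts) {
    m <- lamcal:::ts_as_matrix(ts)[, which(rib$gm_mask)]
    mean(lamcal:::matrixStats_colSds(m) / colMeans(m))
  }
  expect_gt(rel_sd(halves$bold), 5e-3)         # BOLD modulation present
  # division cancels it except for the interleaving offset at transitions
  corr <- bold_correct_vaso(halves$vaso, halves$bold)
  expect_lt(rel_sd(corr) / rel_sd(halves$bold), 0.05)
  expect_lt(rel_sd(corr), 1e-3)
})
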