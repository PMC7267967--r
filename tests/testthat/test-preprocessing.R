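test_that("interleave splitting halves the series and doubles the TR", {
  arr <- array(rnorm(2 * 2 * 1 * 10), dim = c(2, 2, 1, 10))
  ts <- volume_ts(arr, tr_s = 0.824, contrast = "interleaved")
  halves <- split_interleaved(ts)
  expect_equal(dim(halves$vaso$data)[4], 5)
  expect_equal(halves$vaso$tr_s, 1.648)
  expect_equal(halves$bold$tr_s, 1.648)
  expect_equal(halves$vaso$data[, , , 1], arr[, , , 1])
  expect_equal(halves$bold$data[, , , 1], arr[, , , 2])
  expect_equal(halves$vaso$meta$t_offset_s, 0)
  expect_equal(halves$bold$meta$t_offset_s, 0.824)
  # flip flag swaps the roles
  flipped <- split_interleaved(ts, flip = TRUE)
  expect_equal(flipped$vaso$data, halves$bold$data)
  expect_equal(flipped$bold$data, halves$vaso$data)
  # constant series stays constant in both halves
  ch <- split_interleaved(volume_ts(array(7, c(1, 1, 1, 10)), 0.824,
                                    "interleaved"))
  expect_true(all(ch$vaso$data == 7) && all(ch$bold$data == 7))
  expect_error(split_interleaved(volume_ts(arr[, , , 1:9, drop = FALSE],
                                           0.824, "bold")), "interleaved")
})

test_that("split then re-interleave reproduces the input exactly", {
  arr <- array(rnorm(3 * 2 * 1 * 12), dim = c(3, 2, 1, 12))
  ts <- volume_ts(arr, tr_s = 0.824, contrast = "interleaved")
  halves <- split_interleaved(ts)
  back <- interleave(halves$vaso, halves$bold)
  expect_identical(back$data, arr)
  expect_equal(back$tr_s, ts$tr_s)
})

test_that("dynamic division removes multiplicative BOLD contamination", {
  bold <- ts_from_matrix(matrix(rnorm(40, 100, 5), 4, 10), contrast = "bold")
  vaso <- ts_from_matrix(0.4 * t(lamcal:::ts_as_matrix(bold)),
                         contrast = "vaso")
  corr <- bold_correct_vaso(vaso, bold)
  expect_equal(as.numeric(corr$data), rep(0.4, 40), tolerance = 1e-12)
  expect_equal(corr$contrast, "vaso_corrected")
  # zero in the denominator: NaN plus a warning carrying the count
  bold2 <- bold; bold2$data[1, 1, 1, 3] <- 0
  expect_warning(c2 <- bold_correct_vaso(vaso, bold2), "1 non-positive")
  expect_true(is.nan(c2$data[1, 1, 1, 3]))
})

test_that("T1-weighted reference is the nulled/not-nulled mean ratio", {
  arr <- array(0, c(2, 1, 1, 8))
  arr[, , , seq(1, 8, 2)] <- 40   # nulled
  arr[, , , seq(2, 8, 2)] <- 100  # not-nulled
  ts <- volume_ts(arr, 0.824, "interleaved")
  expect_equal(as.numeric(t1w_reference(ts)), c(0.4, 0.4))
  same <- volume_ts(array(5, c(2, 1, 1, 8)), 0.824, "interleaved")
  expect_equal(as.numeric(t1w_reference(same)), c(1, 1))
})

test_that("T1w reference separates GM from the WM-like background", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  sim <- simulate_session(small_gt(), rib, lmap, rest_paradigm(300), "rest")
  t1 <- t1w_reference(sim$ts)
  gm_val <- median(t1[rib$gm_mask])
  wm_val <- median(t1[!rib$gm_mask])
  expect_gt(abs(gm_val - wm_val), 0.05)
})

test_that("linear detrending removes a ramp but preserves the mean", {
  nt <- 50
  tvec <- seq_len(nt)
  ramp <- ts_from_matrix(rbind(3 + 0.25 * tvec), tr_s = 1)
  out <- linear_detrend(ramp)
  expect_equal(as.numeric(out$data), rep(3 + 0.25 * mean(tvec), nt),
               tolerance = 1e-10)
  # idempotence
  out2 <- linear_detrend(out)
  expect_equal(out2$data, out$data, tolerance = 1e-10)
  # ramp + sinusoid: residual slope ~ 0, sinusoid survives
  x <- 2 + 0.1 * tvec + sin(2 * pi * tvec / 8)
  dt <- linear_detrend(ts_from_matrix(rbind(x), tr_s = 1))
  y <- as.numeric(dt$data)
  expect_lt(abs(coef(lm(y ~ tvec))[2]), 1e-3)
  expect_equal(sd(y), sd(sin(2 * pi * tvec / 8)), tolerance = 0.05)
})

test_that("band-pass keeps in-band sinusoids and rejects DC and out-of-band", {
  nt <- 546; tr <- 1.648
  tt <- (seq_len(nt) - 1) * tr
  sin05 <- ts_from_matrix(rbind(sin(2 * pi * 0.05 * tt)), tr_s = tr)
  dc <- ts_from_matrix(rbind(rep(4, nt)), tr_s = tr)
  low <- filter_band("low"); high <- filter_band("high")
  expect_gt(sd(bandpass(sin05, low)$data), 0.95 / sqrt(2))
  expect_lt(sd(bandpass(sin05, high)$data), 0.05 / sqrt(2))
  expect_lt(max(abs(bandpass(dc, low)$data)), 1e-6)
  expect_error(bandpass(sin05, filter_band("custom", 0.01, 0.4)), "Nyquist")
  expect_error(filter_band("custom", 0.2, 0.1), "f_lo < f_hi")
})

test_that("band-pass is linear and has a spectral (brick-wall) variant", {
  set.seed(11)
  nt <- 400; tr <- 1.648
  x <- rnorm(nt); y <- rnorm(nt)
  band <- filter_band("low")
  for (method in c("butterworth", "spectral")) {
    fx <- bandpass(ts_from_matrix(rbind(x), tr_s = tr), band, method)
    fy <- bandpass(ts_from_matrix(rbind(y), tr_s = tr), band, method)
    fxy <- bandpass(ts_from_matrix(rbind(2 * x - 3 * y), tr_s = tr),
                    band, method)
    expect_equal(as.numeric(fxy$data),
                 as.numeric(2 * fx$data - 3 * fy$data), tolerance = 1e-8)
  }
})

test_that("variance partition across disjoint bands holds on broadband noise", {
  set.seed(4)
  nt <- 546; tr <- 1.648
  ts <- ts_from_matrix(matrix(rnorm(20 * nt), 20, nt), tr_s = tr)
  v <- sapply(c("full", "low", "high"), function(b)
    mean(lamcal:::matrixStats_colSds(
      lamcal:::ts_as_matrix(bandpass(ts, filter_band(b))))^2))
  expect_equal(unname(v["low"] + v["high"]) / unname(v["full"]), 1,
               tolerance = 0.1)
})

test_that("physiological phase regression removes in-span oscillations", {
  fs <- 20; dur <- 120; tr <- 1.648
  tp <- seq(0, dur, by = 1 / fs)
  set.seed(3)
  card <- sin(2 * pi * 1.05 * tp) + 0.01 * rnorm(length(tp))
  resp <- sin(2 * pi * 0.29 * tp) + 0.01 * rnorm(length(tp))
  ph <- physio_trace(card, resp, fs)
  tvol <- seq(0, dur - tr, by = tr)
  # cosine of the assigned cardiac phase is exactly in the regressor span
  ph_c <- lamcal:::cardiac_phase(card, fs, tvol)
  sig <- 100 + cos(ph_c)
  ts <- ts_from_matrix(rbind(sig), tr_s = tr)
  out <- retroicor(ts, ph)
  expect_lt(var(as.numeric(out$data)) / var(sig - 100), 0.01)
  expect_equal(mean(out$data), mean(sig), tolerance = 1e-8)
  # a plain cardiac-frequency cosine (phase estimated from peaks) is
  # suppressed to a few percent
  sig2 <- 100 + cos(2 * pi * 1.05 * tvol)
  out2 <- retroicor(ts_from_matrix(rbind(sig2), tr_s = tr), ph)
  expect_lt(var(as.numeric(out2$data)) / var(sig2 - 100), 0.08)
  # a slow drift orthogonal to the physiological regressors is untouched
  drift <- 100 + 0.05 * tvol
  out2 <- retroicor(ts_from_matrix(rbind(drift), tr_s = tr), ph)
  expect_equal(as.numeric(out2$data), drift, tolerance = 0.02)
  # physio recording shorter than the scan is an error
  expect_error(retroicor(ts_from_matrix(rbind(rep(1, 200)), tr_s = tr), ph),
               "shorter")
})

test_that("RETROICOR pulls simulated physio-contaminated variance toward the clean level", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  gt_on <- make_ground_truth(n_laminae = 5, noise_sd = 0.1, rest_amp = 0,
                             physio_amp = 0.01, seed = 6)
  gt_off <- make_ground_truth(n_laminae = 5, noise_sd = 0.1, rest_amp = 0,
                              physio_amp = 0, seed = 6)
  s_on <- simulate_session(gt_on, rib, lmap, rest_paradigm(300), "rest")
  s_off <- simulate_session(gt_off, rib, lmap, rest_paradigm(300), "rest")
  gm_cols <- which(rib$gm_mask)
  voxvar <- function(ts) mean(lamcal:::matrixStats_colSds(
    lamcal:::ts_as_matrix(ts)[, gm_cols])^2)
  b_on <- split_interleaved(s_on$ts)$bold
  b_off <- split_interleaved(s_off$ts)$bold
  corrected <- retroicor(b_on, s_on$physio)
  excess_before <- voxvar(b_on) - voxvar(b_off)
  excess_after <- voxvar(corrected) - voxvar(b_off)
  expect_gt(excess_before, 0)
  expect_lt(excess_after, 0.35 * excess_before)
})
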