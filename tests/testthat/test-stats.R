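test_that("GLM Z-map: perfect response gives huge Z, defaults are 2.3/1.8", {
  p <- mini_hc_paradigm()
  tt <- seq(0, 418, by = 1.648)
  u <- vascular_response(paradigm_boxcar(p, tt), 1.648, 30)
  set.seed(5)
  clean <- 100 + 2 * u
  noisy <- clean + 0.01 * rnorm(length(tt))
  z <- glm_zstat(ts_from_matrix(rbind(noisy), tr_s = 1.648), p)
  expect_gt(as.numeric(z$values), 20)
  expect_equal(z$threshold, 2.3)
  zv <- glm_zstat(ts_from_matrix(rbind(-noisy), tr_s = 1.648,
                                 contrast = "vaso_corrected"), p)
  expect_gt(as.numeric(zv$values), 20)   # sign-inverted regressor
  expect_equal(zv$threshold, 1.8)
  expect_error(glm_zstat(ts_from_matrix(rbind(noisy), tr_s = 1.648),
                         rest_paradigm(418)), "collinear")
})

test_that("GLM null calibration: tail fraction at Z > 2.3 is ~ 0.0107", {
  set.seed(12)
  nvox <- 6000; nt <- 400
  ts <- ts_from_matrix(matrix(rnorm(nvox * nt), nvox, nt), tr_s = 1.648)
  z <- glm_zstat(ts, mini_hc_paradigm())
  frac <- mean(z$values > 2.3)
  p0 <- pnorm(2.3, lower.tail = FALSE)
  se <- sqrt(p0 * (1 - p0) / nvox)
  expect_lt(abs(frac - p0), 4 * se)
})

test_that("conjunction ROI intersects thresholded maps and keeps one blob", {
  gm <- matrix(TRUE, 6, 6)
  mk <- function(vals, thr) structure(list(values = vals, threshold = thr),
                                      class = "zstat_map")
  zb <- mk(matrix(3, 6, 6), 2.3)
  zv <- mk(matrix(2, 6, 6), 1.8)
  expect_true(all(define_roi(zb, zv, gm)))
  # disjoint suprathreshold sets -> error with guidance
  zb2 <- mk(rbind(matrix(3, 3, 6), matrix(0, 3, 6)), 2.3)
  zv2 <- mk(rbind(matrix(0, 3, 6), matrix(2, 3, 6)), 1.8)
  expect_error(define_roi(zb2, zv2, gm), "empty ROI")
  # two components: only the largest survives
  zb3 <- mk(matrix(0, 6, 6), 2.3)
  zb3$values[1:2, 1:2] <- 3       # 4 pixels
  zb3$values[5:6, 4:6] <- 3       # 6 pixels
  roi <- define_roi(zb3, zv, gm)
  expect_equal(sum(roi), 6)
  expect_true(all(roi[5:6, 4:6]))
})

test_that("ROI from a favorable-SNR simulation spans all laminae", {
  rib <- small_ribbon()
  lmap <- grow_equivolume_laminae(rib, 5)
  gt <- make_ground_truth(n_laminae = 5, noise_sd = 0.3, rest_amp = 0,
                          physio_amp = 0)
  sim <- simulate_session(gt, rib, lmap, hypercapnia_paradigm(),
                          "hypercapnia")
  halves <- split_interleaved(sim$ts)
  corr <- bold_correct_vaso(halves$vaso, halves$bold)
  zb <- glm_zstat(linear_detrend(halves$bold), hypercapnia_paradigm())
  zv <- glm_zstat(linear_detrend(corr), hypercapnia_paradigm())
  roi <- define_roi(zb, zv, rib$gm_mask)
  expect_true(all(roi[rib$gm_mask]))           # confined to and filling GM
  expect_false(any(roi[!rib$gm_mask]))
})

test_that("profile normalization: constant scale, proportionality, rescale", {
  bold <- laminar_profile(c(1, 2, 3, 4), quantity = "dS")
  const <- laminar_profile(rep(2, 4), quantity = "RSFA")
  out <- normalize_profile(bold, const, rescale = "mean")
  expect_equal(out$values, bold$values)        # rescale restores the input
  out2 <- normalize_profile(bold, const, rescale = "none")
  expect_equal(out2$values, bold$values / 2)
  prop <- laminar_profile(3 * bold$values, quantity = "RSFA")
  flat <- normalize_profile(bold, prop, rescale = "none")
  expect_equal(flat$values, rep(1 / 3, 4))
  # invariant to rescaling the scale profile by any positive constant
  sc <- laminar_profile(c(2, 1, 4, 5))
  n1 <- normalize_profile(bold, sc)
  n2 <- normalize_profile(bold, laminar_profile(7.3 * sc$values))
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  expect_equal(mean(n1$values), mean(bold$values))  # mean preserved
  # non-positive scale -> NaN with warning
  sc$values[2] <- 0
  expect_warning(n3 <- normalize_profile(bold, sc), "non-positive")
  expect_true(is.nan(n3$values[2]))
  expect_error(normalize_profile(bold, laminar_profile(1:3)), "same number")
})

test_that("task-residual RSFA equals plain RSFA for a null design", {
  set.seed(9)
  ts <- ts_from_matrix(matrix(rnorm(5 * 300, 100), 5, 300), tr_s = 1.648)
  r0 <- rsfa(ts, "full")
  rr <- task_residual_rsfa(ts, rest_paradigm(300 * 1.648), "full")
  expect_equal(rr$values, r0$values, tolerance = 1e-9)
})

test_that("task-residual RSFA of a noiseless response is ~ zero", {
  p <- task_paradigm(600, 30)
  tt <- seq(0, 598, by = 1.648)
  u <- gamma_response(paradigm_boxcar(p, tt), 1.648)
  ts <- ts_from_matrix(rbind(100 + 3 * u), tr_s = 1.648)
  rr <- task_residual_rsfa(ts, p, "full")
  r0 <- rsfa(ts, "full")
  expect_lt(as.numeric(rr$values), 0.02 * as.numeric(r0$values))
})

test_that("laminar regression: exact line, permutation invariance, errors", {
  x <- laminar_profile(seq(0.1, 1.5, length.out = 15))
  y <- laminar_profile(2 * x$values + 1)
  fit <- laminar_regression(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 15)
  set.seed(2)
  xs <- rnorm(15); ys <- rnorm(15)
  o <- sample(15)
  expect_equal(laminar_regression(xs, ys)$r_squared,
               laminar_regression(xs[o], ys[o])$r_squared, tolerance = 1e-12)
  expect_error(laminar_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(laminar_regression(1:2, 1:2), "at least 3")
})

test_that("independent profiles give small R^2 and ~uniform p-values", {
  set.seed(14)
  ps <- replicate(200, laminar_regression(rnorm(15), rnorm(15))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(median(replicate(100,
    laminar_regression(rnorm(15), rnorm(15))$r_squared)), 0.2)
})

test_that("Bland-Altman: identity, offset, and proportional bias", {
  x <- laminar_profile(seq(1, 3, length.out = 10))
  same <- bland_altman(x, x)
  expect_equal(c(same$mean_diff, same$loa_low, same$loa_high), c(0, 0, 0))
  off <- bland_altman(x, laminar_profile(x$values + 3))
  expect_equal(off$mean_diff, 3)
  expect_equal(off$loa_high - off$loa_low, 0)
  # y = 2x: no mean bias after centering but differences track the means
  prop <- bland_altman(x, laminar_profile(2 * x$values))
  expect_gt(abs(cor(prop$diffs, prop$means)), 0.99)
  expect_true(prop$loa_low <= prop$mean_diff &&
                prop$mean_diff <= prop$loa_high)
  # standardization makes a pure rescaling agree exactly
  std <- bland_altman(x, laminar_profile(2 * x$values), standardize = TRUE)
  expect_equal(std$mean_diff, 0, tolerance = 1e-10)
  expect_lt(max(abs(std$diffs)), 1e-10)
})
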