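# Small fixtures shared across test files; everything built in code.

small_ribbon <- function() make_ribbon(12, 24, pi / 2, c(28, 28))

small_gt <- function(...) {
  args <- utils::modifyList(list(n_laminae = 5, noise_sd = 0, rest_amp = 0,
                                 physio_amp = 0), list(...))
  do.call(make_ground_truth, args)
}

# a short hypercapnia-style paradigm for fast simulations (tiled 30-s blocks
# are used where transition shape does not matter)
mini_hc_paradigm <- function() {
  paradigm(data.frame(
    label = c("baseline", "challenge", "baseline", "challenge", "baseline"),
    onset_s = c(0, 60, 150, 240, 330),
    duration_s = c(60, 90, 90, 90, 90)))
}

# deterministic synthetic series: one voxel per value of a matrix of
# timecourses (voxels x time)
ts_from_matrix <- function(tc, tr_s = 1.648, contrast = "bold",
                           t_offset_s = 0) {
  nv <- nrow(tc); nt <- ncol(tc)
  volume_ts(array(tc, dim = c(nv, 1, 1, nt)), tr_s = tr_s,
            contrast = contrast, meta = list(t_offset_s = t_offset_s))
}

constant_ts <- function(value, nt = 10, tr_s = 1.648, contrast = "bold") {
  ts_from_matrix(matrix(value, 1, nt), tr_s = tr_s, contrast = contrast)
}
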