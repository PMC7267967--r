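#' 4D fMRI volume time series
#'
#' The container every pipeline stage consumes and produces: a 4D signal
#' array indexed `(x, y, z, t)` in arbitrary signal units, the effective
#' volume-to-volume repetition time of the series *as stored*, and a
#' contrast label.  For interleaved SS-SI-VASO acquisitions the series
#' alternates blood-nulled (VASO-weighted) and not-nulled (BOLD-weighted)
#' volumes; by convention even time indices (0, 2, ... counting from 0)
#' are the nulled volumes unless `meta$nulled_first` is `FALSE`.
#'
#' @param data 4D numeric array `(x, y, z, t)`.  A 3D array is rejected:
#'   a single volume is not a time series.
#' @param tr_s repetition time in seconds between consecutive stored
#'   volumes (for an interleaved series this is half the effective
#'   per-contrast TR).
#' @param contrast one of `"interleaved"`, `"bold"`, `"vaso"`,
#'   `"vaso_corrected"`.
#' @param meta named list of free-form provenance.  Recognised entries:
#'   `nulled_first` (logical, interleaving order), `t_offset_s` (acquisition
#'   time of the first stored volume relative to paradigm onset).
#' @return an object of class `volume_ts`.
#' @export
volume_ts <- function(data, tr_s, contrast = c("interleaved", "bold", "vaso",
                                               "vaso_corrected"),
                      meta = list()) {
  contrast <- match.arg(contrast)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("not a timeseries: 'data' must be a 4D array (x, y, z, t)")
  nt <- dim(data)[4]
  if (nt < 2L)
    stop("not a timeseries: need at least 2 volumes, got ", nt)
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("'tr_s' must be a single positive number")
  if (contrast == "interleaved" && nt %% 2L != 0L)
    stop("interleaved series must have an even number of volumes, got ", nt)
  if (is.null(meta$t_offset_s)) meta$t_offset_s <- 0
  if (is.null(meta$nulled_first) && contrast == "interleaved")
    meta$nulled_first <- TRUE
  structure(list(data = data, tr_s = tr_s, contrast = contrast, meta = meta),
            class = "volume_ts")
}

#' @export
print.volume_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_ts> %s, %d x %d x %d voxels, %d volumes, TR %.4g s\n",
              x$contrast, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.volume_ts <- function(x) dim(x$data)

n_volumes <- function(ts) dim(ts$data)[4]

#' Acquisition times of the stored volumes
#'
#' Seconds relative to paradigm onset, taking the stored offset of the
#' first volume into account (relevant after interleave splitting).
#' @param ts a [volume_ts()].
#' @return numeric vector of length `dim(ts)[4]`.
#' @export
volume_times <- function(ts) {
  ts$meta$t_offset_s + (seq_len(n_volumes(ts)) - 1) * ts$tr_s
}

#' Block paradigm
#'
#' Ordered, non-overlapping baseline/challenge blocks covering
#' `[0, total_duration_s)`.
#'
#' @param blocks data.frame with columns `label` (`"baseline"` or
#'   `"challenge"`), `onset_s`, `duration_s`.
#' @param total_duration_s total paradigm duration; defaults to the end of
#'   the last block.
#' @return object of class `paradigm`.
#' @export
paradigm <- function(blocks, total_duration_s = NULL) {
  stopifnot(is.data.frame(blocks),
            all(c("label", "onset_s", "duration_s") %in% names(blocks)))
  if (!all(blocks$label %in% c("baseline", "challenge")))
    stop("block labels must be 'baseline' or 'challenge'")
  o <- order(blocks$onset_s)
  blocks <- blocks[o, , drop = FALSE]
  ends <- blocks$onset_s + blocks$duration_s
  if (nrow(blocks) > 1 &&
      any(abs(blocks$onset_s[-1] - ends[-nrow(blocks)]) > 1e-9))
    stop("blocks must tile the paradigm without gaps or overlap")
  if (abs(blocks$onset_s[1]) > 1e-9)
    stop("first block must start at 0")
  if (is.null(total_duration_s)) total_duration_s <- ends[nrow(blocks)]
  if (abs(total_duration_s - ends[nrow(blocks)]) > 1e-9)
    stop("blocks must cover [0, total_duration_s)")
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, total_duration_s = total_duration_s),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("<paradigm> %d blocks, %.0f s total\n",
              nrow(x$blocks), x$total_duration_s))
  print(x$blocks)
  invisible(x)
}

#' Standard gas-challenge paradigm
#'
#' 15-min hypercapnia block design: 2 min room air, 3 min gas, 3 min air,
#' 3 min gas, 4 min air.
#' @return a [paradigm()].
#' @export
hypercapnia_paradigm <- function() {
  paradigm(data.frame(
    label = c("baseline", "challenge", "baseline", "challenge", "baseline"),
    onset_s = c(0, 120, 300, 480, 660),
    duration_s = c(120, 180, 180, 180, 240)))
}

#' Resting-state paradigm
#'
#' A single baseline block (no challenge), default 15 min.
#' @param total_duration_s session length in seconds.
#' @return a [paradigm()].
#' @export
rest_paradigm <- function(total_duration_s = 900) {
  paradigm(data.frame(label = "baseline", onset_s = 0,
                      duration_s = total_duration_s))
}

#' Alternating task block paradigm
#'
#' Baseline/challenge blocks of equal length, starting with baseline,
#' default 24 min of 30-s blocks (finger-tapping style design).
#' @param total_duration_s session length in seconds.
#' @param block_s single block duration in seconds.
#' @return a [paradigm()].
#' @export
task_paradigm <- function(total_duration_s = 1440, block_s = 30) {
  n <- floor(total_duration_s / block_s)
  if (n < 2) stop("paradigm too short for alternating blocks")
  onsets <- (seq_len(n) - 1) * block_s
  dur <- rep(block_s, n)
  dur[n] <- total_duration_s - onsets[n]
  paradigm(data.frame(
    label = rep(c("baseline", "challenge"), length.out = n),
    onset_s = onsets, duration_s = dur))
}

#' Challenge boxcar sampled at given times
#'
#' @param paradigm a [paradigm()].
#' @param times seconds.
#' @return 0/1 vector, 1 inside challenge blocks.
#' @export
paradigm_boxcar <- function(paradigm, times) {
  box <- numeric(length(times))
  ch <- paradigm$blocks[paradigm$blocks$label == "challenge", , drop = FALSE]
  for (i in seq_len(nrow(ch)))
    box[times >= ch$onset_s[i] &
          times < ch$onset_s[i] + ch$duration_s[i]] <- 1
  box
}

has_challenge <- function(paradigm)
  any(paradigm$blocks$label == "challenge")

#' Cardiac and respiratory traces
#'
#' @param cardiac,respiratory numeric vectors of equal length.
#' @param fs_hz sampling rate in Hz.
#' @return object of class `physio_trace`.
#' @export
physio_trace <- function(cardiac, respiratory, fs_hz) {
  if (length(cardiac) != length(respiratory))
    stop("cardiac and respiratory traces must have equal length")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("'fs_hz' must be positive")
  structure(list(fs_hz = fs_hz, cardiac = as.numeric(cardiac),
                 respiratory = as.numeric(respiratory)),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> %d samples at %g Hz (%.1f s)\n",
              length(x$cardiac), x$fs_hz, length(x$cardiac) / x$fs_hz))
  invisible(x)
}
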