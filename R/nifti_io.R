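#' Read a 4D NIfTI time series
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param contrast contrast label; if `NULL` the label stored in the header
#'   description field by [write_timeseries()] is used, falling back to
#'   `"bold"`.
#' @param tr_s override the repetition time from the header (required when
#'   the header TR is missing or zero).
#' @return a [volume_ts()].
#' @export
read_timeseries <- function(path, contrast = NULL, tr_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 4L)
    stop("not a timeseries: ", path, " is not 4D")
  hdr <- RNifti::niftiHeader(img)
  meta <- list()
  if (is.null(contrast)) {
    m <- regmatches(hdr$descrip,
                    regexec("contrast=([a-z_]+)", hdr$descrip))[[1]]
    contrast <- if (length(m) == 2) m[2] else "bold"
  }
  m <- regmatches(hdr$descrip, regexec("t0=([0-9.]+)", hdr$descrip))[[1]]
  if (length(m) == 2) meta$t_offset_s <- as.numeric(m[2])
  if (is.null(tr_s)) tr_s <- hdr$pixdim[5]
  if (!is.finite(tr_s) || tr_s <= 0)
    stop("non-positive TR in header; pass tr_s explicitly")
  arr <- array(as.numeric(img), dim = d)
  volume_ts(arr, tr_s = tr_s, contrast = contrast, meta = meta)
}

#' Write a 4D time series to NIfTI-1
#'
#' The TR is recorded in `pixdim[4]` and the contrast label plus first-volume
#' time offset in the header description field, so that
#' [read_timeseries()] round-trips both.
#'
#' @param ts a [volume_ts()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "volume_ts"))
  img <- RNifti::asNifti(ts$data)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr_s)
  descrip <- sprintf("contrast=%s t0=%g", ts$contrast, ts$meta$t_offset_s)
  img <- RNifti::asNifti(img, reference = list(descrip = descrip))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a 2D/3D map to NIfTI-1
#'
#' @param map 2D or 3D numeric/integer/logical array.
#' @param path output path.
#' @param integer write as 32-bit integers (lamina labels, masks).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, integer = FALSE) {
  if (is.logical(map)) map <- array(as.integer(map), dim = dim(map))
  if (length(dim(map)) == 2L) dim(map) <- c(dim(map), 1L)
  img <- RNifti::asNifti(map)
  RNifti::writeNifti(img, path, datatype = if (integer) "int" else "double")
  invisible(path)
}

#' Read a 2D/3D map written by [write_map()]
#' @param path NIfTI file.
#' @return numeric array with singleton third dimension dropped.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  d <- dim(arr)
  if (length(d) == 3L && d[3] == 1L) dim(arr) <- d[1:2]
  arr
}

#' Read a two-column physiological recording
#'
#' Delimited text, columns: cardiac, respiratory.
#'
#' @param path text file.
#' @param fs_hz sampling rate of the recording in Hz.
#' @return a [physio_trace()].
#' @export
read_physio <- function(path, fs_hz) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = FALSE)
  if (ncol(tab) != 2L)
    stop("physio file must have exactly 2 columns (cardiac, respiratory), ",
         "got ", ncol(tab))
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric rows in physio file")
  physio_trace(tab[[1]], tab[[2]], fs_hz)
}

#' Write a physiological recording as two-column text
#' @param physio a [physio_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_physio <- function(physio, path) {
  stopifnot(inherits(physio, "physio_trace"))
  write.table(data.frame(physio$cardiac, physio$respiratory), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a laminar profile as delimited text
#'
#' One row per lamina: index, depth fraction, value, sem.
#' @param profile a [laminar_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "laminar_profile"))
  write.table(as.data.frame(profile), path, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a laminar profile written by [write_profile()]
#' @param path tab-delimited file.
#' @return a [laminar_profile()].
#' @export
read_profile <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  laminar_profile(tab$value, depth_fractions = tab$depth_fraction,
                  sem = if ("sem" %in% names(tab)) tab$sem else NULL,
                  quantity = if ("quantity" %in% names(tab))
                    as.character(tab$quantity[1]) else "value")
}

#' Read a pipeline configuration file
#'
#' YAML key/value with nesting; entries override the package defaults from
#' [lamcal_config()].
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- lamcal_config()
  cfg[names(user)] <- user
  cfg
}
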