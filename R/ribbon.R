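#' Cortical ribbon geometry on one slice
#'
#' The 2D gray-matter ribbon between two manually defined (or synthetic)
#' borders: the pial (GM/CSF) surface and the GM/WM surface.  Borders are
#' ordered polylines in pixel units; both must run in the same direction so
#' that index-matched points face each other across the ribbon.
#'
#' @param gm_mask 2D logical matrix, `TRUE` inside the ribbon.
#' @param csf_border,wm_border two-column matrices of (x, y) pixel
#'   coordinates (0-based, pixel centers).
#' @param pixel_size_mm length-2 in-plane pixel size `(dx, dy)`.
#' @return object of class `ribbon_geometry`.
#' @export
ribbon_geometry <- function(gm_mask, csf_border, wm_border,
                            pixel_size_mm = c(1, 1)) {
  stopifnot(is.matrix(gm_mask) || length(dim(gm_mask)) == 2L)
  gm_mask <- gm_mask > 0
  if (!any(gm_mask)) stop("empty GM mask")
  csf_border <- as.matrix(csf_border)
  wm_border <- as.matrix(wm_border)
  if (ncol(csf_border) != 2L || ncol(wm_border) != 2L)
    stop("borders must be two-column (x, y) matrices")
  if (n_components(gm_mask) != 1L)
    warning("GM mask is not a single connected component")
  structure(list(gm_mask = gm_mask, csf_border = csf_border,
                 wm_border = wm_border,
                 pixel_size_mm = as.numeric(pixel_size_mm)),
            class = "ribbon_geometry")
}

#' @export
print.ribbon_geometry <- function(x, ...) {
  cat(sprintf("<ribbon_geometry> %d x %d grid, %d GM pixels\n",
              nrow(x$gm_mask), ncol(x$gm_mask), sum(x$gm_mask)))
  invisible(x)
}

#' Synthetic annular-segment ribbon
#'
#' Builds an analytically defined cortical ribbon: the annulus segment
#' between radii `r_wm` (GM/WM border) and `r_csf` (pial border) around the
#' pixel-space origin `center`, spanning `angular_extent` radians starting
#' at angle 0.  Because both borders are concentric circular arcs, the
#' equivolume lamina boundaries have the closed form
#' `r_k = sqrt(((n - k) r_wm^2 + k r_csf^2) / n)`, which makes this the
#' standard oracle fixture for the layering module.
#'
#' @param r_wm,r_csf inner and outer border radii in pixels,
#'   `0 < r_wm < r_csf`.
#' @param angular_extent arc extent in radians, in `(0, 2*pi]`.
#' @param grid_shape `c(nx, ny)` of the pixel grid.
#' @param center arc center in 0-based pixel coordinates; defaults to the
#'   grid origin so that a quarter annulus fills the corner.
#' @return a [ribbon_geometry()] whose borders are densely sampled arcs.
#' @export
make_ribbon <- function(r_wm, r_csf, angular_extent = pi / 2,
                        grid_shape = c(176, 176), center = c(0, 0)) {
  if (!(r_wm > 0 && r_csf > r_wm))
    stop("need 0 < r_wm < r_csf (radii out of order?)")
  if (!(angular_extent > 0 && angular_extent <= 2 * pi + 1e-12))
    stop("angular_extent must be in (0, 2*pi]")
  if (r_csf - r_wm < 3)
    stop("ribbon thinner than 3 pixels")
  nx <- grid_shape[1]; ny <- grid_shape[2]
  x <- (seq_len(nx) - 1) - center[1]
  y <- (seq_len(ny) - 1) - center[2]
  r <- sqrt(outer(x^2, y^2, `+`))
  th <- atan2(rep(y, each = nx), rep(x, times = ny))
  th <- (th + 2 * pi) %% (2 * pi)
  dim(th) <- c(nx, ny)
  full <- angular_extent >= 2 * pi - 1e-12
  gm <- r >= r_wm & r < r_csf & (full | th < angular_extent)
  if (!any(gm)) stop("ribbon does not intersect the grid")
  arc <- function(rad) {
    # ~0.1 px sampling so point-to-polyline distances are effectively exact
    ntheta <- max(64L, ceiling(rad * angular_extent / 0.1))
    theta <- seq(0, angular_extent, length.out = ntheta + 1L)
    if (full) theta <- theta[-length(theta)]
    cbind(x = center[1] + rad * cos(theta), y = center[2] + rad * sin(theta))
  }
  ribbon_geometry(gm, csf_border = arc(r_csf), wm_border = arc(r_wm))
}

# 4-connected component labelling for small 2D masks (BFS).
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  current <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nx + 1L
      j <- (p - 1L) %/% nx + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > nx || nb[2] < 1L || nb[2] > ny) next
        q <- nb[1] + (nb[2] - 1L) * nx
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- current
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

n_components <- function(mask) max(label_components(mask))

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
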