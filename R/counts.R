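# raw stereological tallies on raster masks

coord_to_index <- function(coord, px, n) {
  i <- floor(coord / px) + 1L
  i[i >= 1L & i <= n]
}

#' Count grid points falling on vessel profiles
#'
#' A lattice point scores when the pixel under it is vessel foreground and
#' inside the region of interest. `P_roi`, the number of lattice points
#' inside the ROI, gives the point-count estimate of the reference area
#' (`P_roi * d^2`) used as a cross-check on the pixel-counted ROI area.
#'
#' @param vessel_mask,roi_mask binary rasters of identical dimensions
#'   (see [as_mask()]).
#' @param grid a [generate_grid()] result.
#' @return list with integer counts `P` and `P_roi`.
#' @export
count_points <- function(vessel_mask, roi_mask, grid) {
  stopifnot(inherits(grid, "vm_grid"))
  check_same_raster(vessel_mask, roi_mask, c("vessel mask", "ROI mask"))
  px <- pixel_size(vessel_mask, grid$spec$pixel_size_um)
  v <- as_logical_mask(vessel_mask)
  r <- as_logical_mask(roi_mask)
  cols <- floor(grid$points$x / px) + 1L
  rows <- floor(grid$points$y / px) + 1L
  keep <- rows >= 1L & rows <= nrow(v) & cols >= 1L & cols <= ncol(v)
  idx <- cbind(rows[keep], cols[keep])
  in_roi <- r[idx]
  list(P = sum(v[idx] & in_roi), P_roi = sum(in_roi))
}

# transitions between foreground and background along one pixel profile;
# runs clipped by the field edge contribute 1 per interior end only
n_transitions <- function(v) {
  n <- length(v)
  if (n < 2L) return(0L)
  sum(v[-1] != v[-n])
}

#' Count vessel-boundary intersections with the grid lines
#'
#' Along each horizontal line the vessel mask (restricted to the ROI) is
#' sampled at pixel resolution and foreground/background transitions are
#' counted: a profile traversed by a line contributes 2 (entry and exit);
#' runs clipped by the field edge contribute only their interior crossing.
#' `hI` collects crossings of horizontal lines, `vI` of vertical lines.
#'
#' @inheritParams count_points
#' @return list with integer counts `hI` and `vI`.
#' @export
count_intersections <- function(vessel_mask, roi_mask, grid) {
  stopifnot(inherits(grid, "vm_grid"))
  check_same_raster(vessel_mask, roi_mask, c("vessel mask", "ROI mask"))
  px <- pixel_size(vessel_mask, grid$spec$pixel_size_um)
  fg <- as_logical_mask(vessel_mask) & as_logical_mask(roi_mask)
  rows <- coord_to_index(grid$y, px, nrow(fg))
  cols <- coord_to_index(grid$x, px, ncol(fg))
  hI <- sum(vapply(rows, function(r) n_transitions(fg[r, ]), integer(1)))
  vI <- sum(vapply(cols, function(c) n_transitions(fg[, c]), integer(1)))
  list(hI = hI, vI = vI)
}

#' Count vessel profiles with an unbiased counting frame
#'
#' Distinct labelled profiles intersecting the frame are counted once each,
#' except profiles touching a forbidden edge. The left and bottom frame
#' edges (with their full-line extensions) are forbidden, the right and top
#' edges are inclusion edges, so each profile in a homogeneous field has
#' equal counting probability.
#'
#' @param labelled_mask integer raster, 0 = background, one positive ID per
#'   profile.
#' @param frame counting frame in micrometres as
#'   `c(x_min, x_max, y_min, y_max)`; default the whole field.
#' @param pixel_size_um pixel size; taken from the mask attribute if absent.
#' @return integer profile count `N`.
#' @export
count_profiles <- function(labelled_mask, frame = NULL, pixel_size_um = NULL) {
  px <- pixel_size(labelled_mask, pixel_size_um)
  lab <- labelled_mask
  if (is.logical(lab)) abort("count_profiles needs a labelled (integer) mask, not a binary one")
  nr <- nrow(lab); nc <- ncol(lab)
  if (is.null(frame)) frame <- c(0, nc * px, 0, nr * px)
  c0 <- max(1L, floor(frame[1] / px) + 1L)
  c1 <- min(nc, ceiling(frame[2] / px))
  r0 <- max(1L, floor(frame[3] / px) + 1L)
  r1 <- min(nr, ceiling(frame[4] / px))
  if (c0 > c1 || r0 > r1) return(0L)
  inside <- setdiff(unique(as.vector(lab[r0:r1, c0:c1])), 0)
  # forbidden: left frame-edge column and bottom frame-edge row, extended
  forbidden <- union(unique(lab[, c0]), unique(lab[r1, ]))
  length(setdiff(inside, forbidden))
}

#' Boundary length from line-intersection counts
#'
#' The classical intercept estimator: with `L = (hI + vI)/2` the raw
#' boundary length is `B = 0.5 * pi * L * d`. Dividing by the reference
#' area reproduces the (pi/2) I_L surface-density estimator for a square
#' grid whose total test-line length is `2 * area / d`.
#'
#' @param hI,vI intersection counts with horizontal and vertical lines.
#' @param pitch_um grid pitch `d` in micrometres.
#' @return boundary length in micrometres.
#' @examples
#' boundary_length(10, 10, 12.25)   # 0.5 * pi * 10 * 12.25 = 192.42 um
#' @export
boundary_length <- function(hI, vI, pitch_um = 12.25) {
  if (any(hI < 0, na.rm = TRUE) || any(vI < 0, na.rm = TRUE))
    abort("intersection counts must be non-negative")
  if (pitch_um <= 0) abort("pitch_um must be > 0")
  0.5 * pi * (hI + vI) / 2 * pitch_um
}

#' Profile area from point counts
#'
#' Each lattice point represents `d^2` of area (150.0625 um^2 at the
#' default 12.25 um pitch), so `A = d^2 * P`.
#'
#' @param P number of points over vessel profiles.
#' @param pitch_um grid pitch `d` in micrometres.
#' @return area in square micrometres.
#' @examples
#' point_count_area(1)   # 150.0625
#' @export
point_count_area <- function(P, pitch_um = 12.25) {
  if (any(P < 0, na.rm = TRUE)) abort("point counts must be non-negative")
  pitch_um^2 * P
}
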