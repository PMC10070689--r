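#' Specify a square stereological test grid
#'
#' The test system is a square lattice of horizontal and vertical lines with
#' pitch `d`; the lattice points at their crossings are point probes (each
#' representing an area of d^2, nominally 150 um^2 at the default pitch of
#' 12.25 um), the lines are intersection probes for boundary length.
#'
#' @param pitch_um line spacing `d` in micrometres. The default 12.25 um
#'   gives d^2 = 150.0625 um^2 per point.
#' @param field_width_um,field_height_um field extent in micrometres
#'   (defaults 318 x 429, one micrograph field).
#' @param pixel_size_um physical pixel size used when the grid is applied to
#'   rasters, micrometres per pixel.
#' @param offset_x_um,offset_y_um optional fixed grid offsets in
#'   `[0, pitch)`; if `NULL` (default) they are drawn uniformly when the
#'   grid is generated, which is what makes the point/intersection counts
#'   unbiased under random placement.
#' @return a `grid_spec` list.
#' @examples
#' grid_spec()                        # the default 150 um^2-per-point grid
#' grid_spec(pitch_um = 25)
#' @export
grid_spec <- function(pitch_um = 12.25,
                      field_width_um = 318,
                      field_height_um = 429,
                      pixel_size_um = 0.33,
                      offset_x_um = NULL,
                      offset_y_um = NULL) {
  if (!is.numeric(pitch_um) || pitch_um <= 0) abort("pitch_um must be > 0")
  if (field_width_um <= pitch_um)
    abort(sprintf("field_width_um (%g) must exceed the pitch (%g): no vertical line fits",
                  field_width_um, pitch_um))
  if (field_height_um <= pitch_um)
    abort(sprintf("field_height_um (%g) must exceed the pitch (%g): no horizontal line fits",
                  field_height_um, pitch_um))
  for (off in list(offset_x_um, offset_y_um)) {
    if (!is.null(off) && (off < 0 || off >= pitch_um))
      abort("grid offsets must lie in [0, pitch)")
  }
  structure(
    list(pitch_um = pitch_um,
         field_width_um = field_width_um,
         field_height_um = field_height_um,
         pixel_size_um = pixel_size_um,
         offset_x_um = offset_x_um,
         offset_y_um = offset_y_um,
         area_per_point_um2 = pitch_um^2),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> pitch %.4g um (%.4g um^2/point), field %g x %g um, %g um/px\n",
              x$pitch_um, x$area_per_point_um2,
              x$field_width_um, x$field_height_um, x$pixel_size_um))
  invisible(x)
}

#' Generate a randomly offset test grid over a field
#'
#' Lines are placed at `offset + k * pitch` for integer `k`, keeping those
#' strictly inside the open field interval. Offsets, unless fixed in the
#' spec, are drawn uniformly on `[0, pitch)` from the seeded RNG; with a
#' uniform offset the expected number of lines per family is exactly
#' width/pitch, which is what makes the point-count and line-intersection
#' estimators unbiased.
#'
#' @param spec a [grid_spec()].
#' @param seed integer seed for the offset draw (ignored when both offsets
#'   are fixed in `spec`).
#' @return a `vm_grid` list: `x` (vertical-line abscissae), `y`
#'   (horizontal-line ordinates), `points` (tibble of lattice crossings),
#'   the realised offsets and the spec.
#' @examples
#' g <- generate_grid(grid_spec(offset_x_um = 0, offset_y_um = 0))
#' length(g$x); length(g$y); nrow(g$points)   # 25, 35, 875
#' @export
generate_grid <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  d <- spec$pitch_um
  offs <- with_seed(seed, {
    c(x = spec$offset_x_um %||% runif(1, 0, d),
      y = spec$offset_y_um %||% runif(1, 0, d))
  })
  line_family <- function(offset, extent) {
    v <- seq(offset, extent, by = d)
    v[v > 0 & v < extent]
  }
  xs <- line_family(offs[["x"]], spec$field_width_um)
  ys <- line_family(offs[["y"]], spec$field_height_um)
  structure(
    list(x = xs, y = ys,
         points = tidyr::expand_grid(x = xs, y = ys),
         offset_x_um = offs[["x"]], offset_y_um = offs[["y"]],
         seed = seed, spec = spec),
    class = "vm_grid")
}

#' @export
print.vm_grid <- function(x, ...) {
  cat(sprintf("<vm_grid> %d vertical x %d horizontal lines, %d points, offset (%.3f, %.3f) um\n",
              length(x$x), length(x$y), nrow(x$points),
              x$offset_x_um, x$offset_y_um))
  invisible(x)
}
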