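# synthetic vessel scenes: ellipse profiles with exact geometric ground truth

#' Exact ellipse circumference
#'
#' Complete elliptic integral of the second kind via `pracma::ellipke`:
#' perimeter = 4 a E(m) with m = 1 - (b/a)^2.
#'
#' @param a,b semi-major and semi-minor axes (a >= b > 0), vectorised.
#' @return circumference, same units as the axes.
#' @export
ellipse_perimeter <- function(a, b) {
  stopifnot(all(b > 0), all(a >= b))
  m <- 1 - (b / a)^2
  e <- vapply(m, function(mi) pracma::ellipke(mi)$e, numeric(1))
  4 * a * e
}

#' Build a vessel scene from explicit ellipse profiles
#'
#' A scene is a tibble of elliptical vessel profiles (centre, semi-axes,
#' orientation, all in micrometres/radians) over a rectangular field, with
#' exact ground truth attached.
#'
#' @param profiles tibble/data frame with columns `x_um`, `y_um`, `a_um`,
#'   `b_um`, `theta_rad`.
#' @param field_width_um,field_height_um field extent.
#' @return a `vessel_scene` tibble.
#' @export
vessel_scene <- function(profiles,
                         field_width_um = 318, field_height_um = 429) {
  profiles <- tibble::as_tibble(profiles)
  req <- c("x_um", "y_um", "a_um", "b_um", "theta_rad")
  if (!all(req %in% names(profiles)))
    abort(paste("profiles must have columns:", paste(req, collapse = ", ")))
  if (nrow(profiles) > 0 && any(profiles$b_um <= 0 | profiles$a_um < profiles$b_um))
    abort("each profile needs a_um >= b_um > 0")
  structure(profiles,
            field_width_um = field_width_um,
            field_height_um = field_height_um,
            class = c("vessel_scene", class(profiles)))
}

#' Exact ground truth of a scene
#'
#' @param scene a [vessel_scene()].
#' @return tibble with `n_profiles`, `total_perimeter_um`, `total_area_um2`.
#' @export
scene_truth <- function(scene) {
  stopifnot(inherits(scene, "vessel_scene"))
  if (nrow(scene) == 0)
    return(tibble::tibble(n_profiles = 0L, total_perimeter_um = 0,
                          total_area_um2 = 0))
  tibble::tibble(
    n_profiles = nrow(scene),
    total_perimeter_um = sum(ellipse_perimeter(scene$a_um, scene$b_um)),
    total_area_um2 = sum(pi * scene$a_um * scene$b_um))
}

# squared-normalised ellipse coordinate: <=1 inside
ellipse_inside <- function(px_x, px_y, x0, y0, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  dx <- px_x - x0; dy <- px_y - y0
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / a)^2 + (v / b)^2 <= 1
}

#' Rasterise a vessel scene to a mask
#'
#' A pixel is foreground iff its centre lies inside any ellipse. With the
#' default 0.33 um/px the rasterised area of profiles with b >= 1 um is
#' within ~1% of the analytic area. `labelled = TRUE` writes the profile
#' row index instead of 1 (later profiles overwrite earlier on overlap,
#' which the default non-overlapping scenes never exercise).
#'
#' @param scene a [vessel_scene()].
#' @param pixel_size_um micrometres per pixel.
#' @param labelled write integer profile IDs instead of a binary mask.
#' @return a [as_mask()] matrix (rows = y).
#' @export
render_scene <- function(scene, pixel_size_um = 0.33, labelled = FALSE) {
  stopifnot(inherits(scene, "vessel_scene"))
  W <- attr(scene, "field_width_um"); H <- attr(scene, "field_height_um")
  nc <- ceiling(W / pixel_size_um); nr <- ceiling(H / pixel_size_um)
  if (nrow(scene) > 0 && min(scene$b_um) / pixel_size_um < 3)
    abort(sprintf("pixel size %g um too coarse for the smallest profile (b = %g um); need b/px >= 3",
                  pixel_size_um, min(scene$b_um)))
  m <- matrix(0L, nr, nc)
  if (nrow(scene) > 0) {
    xc <- (seq_len(nc) - 0.5) * pixel_size_um
    yc <- (seq_len(nr) - 0.5) * pixel_size_um
    for (i in seq_len(nrow(scene))) {
      p <- scene[i, ]
      ext <- p$a_um + pixel_size_um
      cs <- which(xc >= p$x_um - ext & xc <= p$x_um + ext)
      rs <- which(yc >= p$y_um - ext & yc <= p$y_um + ext)
      if (length(cs) == 0 || length(rs) == 0) next
      gx <- matrix(xc[cs], length(rs), length(cs), byrow = TRUE)
      gy <- matrix(yc[rs], length(rs), length(cs))
      ins <- ellipse_inside(gx, gy, p$x_um, p$y_um, p$a_um, p$b_um, p$theta_rad)
      sub <- m[rs, cs, drop = FALSE]
      sub[ins] <- if (labelled) i else 1L
      m[rs, cs] <- sub
    }
  }
  if (!labelled) m <- m != 0L
  as_mask(m, pixel_size_um)
}

#' Sample a synthetic capillary-profile scene
#'
#' Profiles are ellipses from a tilted-cylinder model: a capillary of lumen
#' radius r cut at tilt angle theta from transverse yields a profile with
#' semi-minor b = r and semi-major a = r / cos(theta). Radii are log-normal,
#' tilts uniform on `[0, tilt_max]`; the profile count is Poisson with mean
#' `density * field area`, and profiles are placed uniformly, by default
#' entirely inside the field and non-overlapping (rejection sampling).
#'
#' @param density_per_mm2 expected profile density (mm^-2).
#' @param field_width_um,field_height_um field extent.
#' @param radius_median_um,radius_sdlog log-normal lumen-radius parameters.
#' @param tilt_max_rad maximum cut obliquity (default 60 degrees).
#' @param placement `"inside"` keeps profiles wholly inside the field
#'   (exact full-ellipse ground truth); `"uniform"` places centres uniformly
#'   and lets profiles overhang the edges (for counting-frame studies).
#' @param overlap allow overlapping profiles (skips rejection).
#' @param seed integer seed.
#' @param n_profiles optional fixed count overriding the Poisson draw.
#' @return a [vessel_scene()].
#' @export
sample_profiles <- function(density_per_mm2,
                            field_width_um = 318, field_height_um = 429,
                            radius_median_um = 4, radius_sdlog = 0.25,
                            tilt_max_rad = pi / 3,
                            placement = c("inside", "uniform"),
                            overlap = FALSE, seed = NULL, n_profiles = NULL) {
  placement <- match.arg(placement)
  with_seed(seed, {
    area_mm2 <- field_width_um * field_height_um / 1e6
    n <- n_profiles %||% rpois(1, density_per_mm2 * area_mm2)
    if (n == 0) {
      empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                              a_um = numeric(), b_um = numeric(),
                              theta_rad = numeric())
      return(vessel_scene(empty, field_width_um, field_height_um))
    }
    r <- rlnorm(n, log(radius_median_um), radius_sdlog)
    tilt <- runif(n, 0, tilt_max_rad)
    a <- r / cos(tilt); b <- r
    phi <- runif(n, 0, pi)
    xs <- ys <- numeric(n)
    max_try <- 200L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(max_try)) {
        if (placement == "inside") {
          if (2 * a[i] >= field_width_um || 2 * a[i] >= field_height_um)
            abort("profile larger than the field; reduce radius or enlarge field")
          x <- runif(1, a[i], field_width_um - a[i])
          y <- runif(1, a[i], field_height_um - a[i])
        } else {
          x <- runif(1, 0, field_width_um)
          y <- runif(1, 0, field_height_um)
        }
        if (overlap || i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          # conservative bounding-circle separation
          ok <- all((x - xs[j])^2 + (y - ys[j])^2 > (a[i] + a[j])^2)
        }
        if (ok) { xs[i] <- x; ys[i] <- y; placed <- TRUE; break }
      }
      if (!placed)
        abort("rejection packing failed (density too high for non-overlapping placement); consider overlap = TRUE")
    }
    vessel_scene(tibble::tibble(x_um = xs, y_um = ys, a_um = a, b_um = b,
                                theta_rad = phi),
                 field_width_um, field_height_um)
  })
}
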