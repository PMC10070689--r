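# per-field normalization and the cavity-exclusion rule

#' Exclude lesion cavity from the reference area
#'
#' The effective region of interest is the ROI minus the cavity. When the
#' cavity occupies essentially the whole ROI (fraction at or above
#' `threshold`, default 0.95) the field is flagged missing and contributes
#' no estimates — missing fields propagate as absent values, never zeros,
#' so cavitated epicentre fields do not drag group means down artefactually.
#'
#' @param roi_mask,cavity_mask aligned binary rasters; `cavity_mask` may be
#'   `NULL` (no cavity).
#' @param threshold cavity fraction at which the whole field is dropped.
#' @return list: `roi` (effective ROI mask), `cavity_fraction`, `missing`.
#' @export
apply_cavity_rule <- function(roi_mask, cavity_mask = NULL, threshold = 0.95) {
  r <- as_logical_mask(roi_mask)
  if (is.null(cavity_mask)) {
    cavity_fraction <- 0
    eff <- r
  } else {
    check_same_raster(roi_mask, cavity_mask, c("ROI mask", "cavity mask"))
    cv <- as_logical_mask(cavity_mask)
    n_roi <- sum(r)
    cavity_fraction <- if (n_roi == 0) 1 else sum(r & cv) / n_roi
    eff <- r & !cv
  }
  eff <- as_mask(unclass(eff), pixel_size(roi_mask, attr(roi_mask, "pixel_size_um") %||% 0.33))
  list(roi = eff, cavity_fraction = cavity_fraction,
       missing = cavity_fraction >= threshold)
}

#' Normalise raw field counts to the reference area
#'
#' Converts raw tallies to the four morphometric read-outs: numerical
#' density N_A (profiles per mm^2), boundary/surface density B_A (um of
#' perimeter per mm^2), areal density A_A (um^2 of profile per mm^2), and
#' the surface-to-volume ratio S/V = B_A / A_A (um^-1; ~2/r for round
#' profiles of radius r, larger for collapsed or obliquely cut vessels).
#'
#' @param counts data frame with columns `points_on_vessel`,
#'   `intersections_h`, `intersections_v`, `profile_count`, `roi_area_mm2`,
#'   `cavity_fraction` and logical `missing` (one row per field).
#' @param pitch_um grid pitch in micrometres.
#' @return the input tibble with columns `vessel_density_per_mm2`,
#'   `surface_density_um_per_mm2`, `areal_density_um2_per_mm2`,
#'   `surface_to_volume_per_um` appended (all `NA` where `missing`).
#' @export
normalize_field <- function(counts, pitch_um = 12.25) {
  counts <- tibble::as_tibble(counts)
  req <- c("points_on_vessel", "intersections_h", "intersections_v",
           "profile_count", "roi_area_mm2")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0)
    abort(paste("normalize_field: missing columns:", paste(miss, collapse = ", ")))
  if (!"missing" %in% names(counts)) counts$missing <- FALSE
  bad <- !counts$missing & counts$roi_area_mm2 <= 0
  if (any(bad))
    abort(sprintf("field(s) %s have zero ROI area but are not flagged missing; this indicates a segmentation failure, not a cavity",
                  paste(which(bad), collapse = ", ")))
  out <- dplyr::mutate(
    counts,
    vessel_density_per_mm2 =
      ifelse(.data$missing, NA_real_, .data$profile_count / .data$roi_area_mm2),
    surface_density_um_per_mm2 =
      ifelse(.data$missing, NA_real_,
             boundary_length(.data$intersections_h, .data$intersections_v, pitch_um) /
               .data$roi_area_mm2),
    areal_density_um2_per_mm2 =
      ifelse(.data$missing, NA_real_,
             point_count_area(.data$points_on_vessel, pitch_um) / .data$roi_area_mm2))
  dplyr::mutate(
    out,
    surface_to_volume_per_um = ifelse(
      !.data$missing & .data$areal_density_um2_per_mm2 > 0,
      .data$surface_density_um_per_mm2 / .data$areal_density_um2_per_mm2,
      NA_real_))
}

#' Quantify one field: counts plus normalised estimates
#'
#' Runs the full per-field read-out: draws (or reuses) a random-offset grid,
#' applies the cavity rule, tallies point hits, line intersections and
#' frame-counted profiles, and normalises to the effective ROI area.
#'
#' @param vessel_mask binary vessel-profile raster.
#' @param roi_mask binary ROI raster (default: whole field).
#' @param cavity_mask optional binary cavity raster.
#' @param labelled_mask optional labelled profile raster; if absent,
#'   connected components of the vessel mask are labelled with
#'   `EBImage::bwlabel()`.
#' @param spec a [grid_spec()]; pixel size defaults to the mask's.
#' @param seed integer seed for the grid offset.
#' @param cavity_threshold see [apply_cavity_rule()].
#' @return one-row tibble with raw counts, grid metadata and the
#'   [normalize_field()] estimates.
#' @export
quantify_field <- function(vessel_mask, roi_mask = NULL, cavity_mask = NULL,
                           labelled_mask = NULL, spec = NULL, seed = NULL,
                           cavity_threshold = 0.95) {
  px <- pixel_size(vessel_mask, spec$pixel_size_um %||% 0.33)
  if (is.null(spec))
    spec <- grid_spec(field_width_um = ncol(vessel_mask) * px,
                      field_height_um = nrow(vessel_mask) * px,
                      pixel_size_um = px)
  if (is.null(roi_mask))
    roi_mask <- as_mask(matrix(TRUE, nrow(vessel_mask), ncol(vessel_mask)), px)
  cav <- apply_cavity_rule(roi_mask, cavity_mask, cavity_threshold)
  grid <- generate_grid(spec, seed)

  if (cav$missing) {
    counts <- tibble::tibble(points_on_vessel = NA_integer_,
                             intersections_h = NA_integer_,
                             intersections_v = NA_integer_,
                             profile_count = NA_integer_,
                             roi_area_mm2 = sum(cav$roi) * px^2 / 1e6,
                             cavity_fraction = cav$cavity_fraction,
                             missing = TRUE)
  } else {
    pts <- count_points(vessel_mask, cav$roi, grid)
    ints <- count_intersections(vessel_mask, cav$roi, grid)
    if (is.null(labelled_mask)) {
      fg <- as_logical_mask(vessel_mask) & cav$roi
      labelled_mask <- as_mask(EBImage::bwlabel(fg * 1L), px)
    }
    N <- count_profiles(labelled_mask, pixel_size_um = px)
    counts <- tibble::tibble(points_on_vessel = pts$P,
                             intersections_h = ints$hI,
                             intersections_v = ints$vI,
                             profile_count = N,
                             roi_area_mm2 = sum(cav$roi) * px^2 / 1e6,
                             cavity_fraction = cav$cavity_fraction,
                             missing = FALSE)
  }
  est <- normalize_field(counts, spec$pitch_um)
  dplyr::mutate(est,
                grid_seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                offset_x_um = grid$offset_x_um,
                offset_y_um = grid$offset_y_um,
                .after = "missing")
}
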