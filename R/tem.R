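# orthogonal-thickness morphometry from electron-microscopy contour traces

as_trace <- function(tr) {
  tr <- tibble::as_tibble(tr)
  if (!all(c("x_nm", "y_nm") %in% names(tr)))
    abort("a trace needs columns x_nm and y_nm")
  if (nrow(tr) < 3) abort("a trace needs at least 3 points")
  if (!all(is.finite(tr$x_nm)) || !all(is.finite(tr$y_nm)))
    abort("trace coordinates must be finite")
  tr
}

# unit tangent at vertex i by central difference (one-sided at the ends)
trace_tangent <- function(tr, i) {
  n <- nrow(tr)
  j0 <- max(1L, i - 1L); j1 <- min(n, i + 1L)
  t <- c(tr$x_nm[j1] - tr$x_nm[j0], tr$y_nm[j1] - tr$y_nm[j0])
  len <- sqrt(sum(t^2))
  if (len < .Machine$double.eps^0.5) return(NULL)
  t / len
}

# first crossing of ray p + s*dir (s > eps) with an open polyline;
# returns +Inf when the ray misses
ray_polyline_distance <- function(p, dir, poly) {
  ax <- poly$x_nm[-nrow(poly)]; ay <- poly$y_nm[-nrow(poly)]
  bx <- poly$x_nm[-1]; by <- poly$y_nm[-1]
  ex <- bx - ax; ey <- by - ay
  # solve p + s*dir = a + u*e  =>  [dir, -e] [s, u]' = a - p
  det <- dir[1] * (-ey) - dir[2] * (-ex)
  rx <- ax - p[1]; ry <- ay - p[2]
  s <- (rx * (-ey) - ry * (-ex)) / det
  u <- (dir[1] * ry - dir[2] * rx) / det
  ok <- is.finite(s) & abs(det) > 1e-12 & s > 1e-9 & u >= 0 & u <= 1
  if (!any(ok)) Inf else min(s[ok])
}

#' Orthogonal thickness at one point of a boundary-trace pair
#'
#' Estimates the local tangent of the inner trace at `index` by central
#' difference, casts a ray along the local normal (both directions) and
#' returns the distance to the first crossing of the outer trace — the
#' thickness measured perpendicular to the tangent of the curved structure.
#' Returns `NA` (with a warning) when the tangent is degenerate or no
#' crossing lies within the sanity bound.
#'
#' @param inner,outer ordered point tables (`x_nm`, `y_nm`); nm coordinates.
#' @param index vertex index on the inner trace where thickness is taken.
#' @param max_nm sanity bound: thicknesses beyond this are treated as
#'   misses (these structures are well under 1000 nm).
#' @return thickness in nm, or `NA_real_`.
#' @export
orthogonal_thickness <- function(inner, outer, index, max_nm = 1000) {
  inner <- as_trace(inner); outer <- as_trace(outer)
  if (index < 1 || index > nrow(inner)) abort("index outside the inner trace")
  tg <- trace_tangent(inner, index)
  if (is.null(tg)) {
    warn(sprintf("degenerate tangent at inner vertex %d; measurement skipped", index))
    return(NA_real_)
  }
  nrm <- c(-tg[2], tg[1])
  p <- c(inner$x_nm[index], inner$y_nm[index])
  s <- min(ray_polyline_distance(p, nrm, outer),
           ray_polyline_distance(p, -nrm, outer))
  if (!is.finite(s) || s > max_nm) {
    warn(sprintf("normal ray at inner vertex %d misses the outer trace within %g nm; measurement skipped",
                 index, max_nm))
    return(NA_real_)
  }
  s
}

#' Measure a boundary-trace pair at equidistant sample points
#'
#' Places `n_samples` points equidistantly along the inner trace's arc
#' length (snapping to the nearest vertex, where the tangent is defined)
#' and measures the orthogonal thickness at each. Defaults follow the
#' sampling the study prescribes: 8 points for basement membranes, 4 for
#' intercellular clefts, comfortably above the minimum-sampling rule.
#'
#' @param inner,outer ordered point tables (nm).
#' @param structure `"basement_membrane"` or `"intercellular_cleft"`.
#' @param capillary_id,segment,region,group sample-key tags carried into
#'   the output.
#' @param n_samples number of sample points; default by structure.
#' @param max_nm sanity bound passed to [orthogonal_thickness()].
#' @return tibble of thickness measurements (misses dropped).
#' @export
measure_trace_pair <- function(inner, outer,
                               structure = c("basement_membrane",
                                             "intercellular_cleft"),
                               capillary_id = "cap1", segment = "T10",
                               region = "VG", group = "sham",
                               n_samples = NULL, max_nm = 1000) {
  structure <- match.arg(structure)
  inner <- as_trace(inner)
  n_samples <- n_samples %||%
    switch(structure, basement_membrane = 8L, intercellular_cleft = 4L)
  seg_len <- sqrt(diff(inner$x_nm)^2 + diff(inner$y_nm)^2)
  arc <- c(0, cumsum(seg_len))
  targets <- seq(0, arc[length(arc)], length.out = n_samples + 1L)[-(n_samples + 1L)]
  idx <- unique(vapply(targets, function(t) which.min(abs(arc - t)), integer(1)))
  th <- vapply(idx, function(i)
    suppressWarnings(orthogonal_thickness(inner, outer, i, max_nm)), numeric(1))
  keep <- !is.na(th)
  tibble::tibble(thickness_nm = th[keep], structure = structure,
                 capillary_id = capillary_id, segment = segment,
                 region = region, group = group,
                 sample_index = seq_along(th)[keep])
}

#' Apply the minimum-sampling rule per capillary
#'
#' Capillaries with fewer than `min_bm` basement-membrane or `min_cleft`
#' cleft measurements are excluded from that structure's summary; survivors
#' are reduced to per-capillary means.
#'
#' @param measurements thickness-measurement tibble (as produced by
#'   [measure_trace_pair()] or [simulate_tem()]).
#' @param min_bm,min_cleft minimum measurements per capillary (defaults 4
#'   and 2).
#' @return tibble of per-capillary records: key columns, `n_measurements`,
#'   `mean_nm`.
#' @export
enforce_sampling <- function(measurements, min_bm = 4, min_cleft = 2) {
  measurements <- tibble::as_tibble(measurements)
  mins <- c(basement_membrane = min_bm, intercellular_cleft = min_cleft)
  measurements |>
    dplyr::group_by(.data$group, .data$segment, .data$region,
                    .data$structure, .data$capillary_id) |>
    dplyr::summarise(n_measurements = dplyr::n(),
                     mean_nm = mean(.data$thickness_nm), .groups = "drop") |>
    dplyr::filter(.data$n_measurements >= mins[.data$structure])
}

#' Group-level thickness summaries
#'
#' Pools measurements within group x location x structure and reports mean,
#' SD and n. `unit = "measurement"` (default) pools technical replicates,
#' matching figures that plot individual measurements; `unit = "capillary"`
#' first reduces to per-capillary means via [enforce_sampling()].
#'
#' @param measurements thickness-measurement tibble.
#' @param unit pooling level.
#' @param ... passed to [enforce_sampling()] when `unit = "capillary"`.
#' @return tibble `group, segment, region, structure, mean_nm, sd_nm, n`.
#' @export
tem_summary <- function(measurements, unit = c("measurement", "capillary"),
                        ...) {
  unit <- match.arg(unit)
  x <- if (unit == "capillary") {
    dplyr::rename(enforce_sampling(measurements, ...), thickness_nm = "mean_nm")
  } else tibble::as_tibble(measurements)
  x |>
    dplyr::group_by(.data$group, .data$segment, .data$region, .data$structure) |>
    dplyr::summarise(mean_nm = mean(.data$thickness_nm),
                     sd_nm = ifelse(dplyr::n() > 1, sd(.data$thickness_nm), 0),
                     n = dplyr::n(), .groups = "drop")
}

#' Percent change of an injured mean relative to sham
#'
#' `100 * (injured - sham) / sham`, rounded to one decimal; positive values
#' are increases (e.g. cleft widening 16.00 -> 27.28 nm is +70.5%).
#'
#' @param sham_mean,injured_mean group means (same units); `sham_mean > 0`.
#' @return percent change, one decimal place.
#' @examples
#' percent_change(16.00, 27.28)   # 70.5
#' @export
percent_change <- function(sham_mean, injured_mean) {
  if (any(sham_mean <= 0)) abort("sham_mean must be > 0")
  round(100 * (injured_mean - sham_mean) / sham_mean, 1)
}
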