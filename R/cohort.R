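# hierarchical aggregation and spatiotemporal summaries

estimate_cols <- c("vessel_density_per_mm2", "surface_density_um_per_mm2",
                   "areal_density_um2_per_mm2", "surface_to_volume_per_um")

#' Aggregate field estimates to per-animal means
#'
#' Means of means: fields are averaged within each replicate section, then
#' sections within each animal x segment x region cell, weighting sections
#' equally. Missing (cavitated) fields are excluded from denominators;
#' animal-cells whose fields are all missing are absent from the output.
#'
#' @param fields tidy per-field table with the sample-key columns
#'   (`animal_id`, `group`, `segment`, `region`, `section_replicate`) and
#'   any of the four estimate columns.
#' @return tibble of per-animal means by (group, segment, region).
#' @export
aggregate_to_animal <- function(fields) {
  fields <- tibble::as_tibble(fields)
  have <- intersect(estimate_cols, names(fields))
  if (length(have) == 0)
    abort("no estimate columns found; expected one of vessel_density_per_mm2, surface_density_um_per_mm2, areal_density_um2_per_mm2, surface_to_volume_per_um")
  sect <- fields |>
    dplyr::group_by(.data$animal_id, .data$group, .data$segment, .data$region,
                    .data$section_replicate) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(have),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  sect |>
    dplyr::group_by(.data$animal_id, .data$group, .data$segment, .data$region) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(have),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(have),
                                ~ ifelse(is.nan(.x), NA_real_, .x))) |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(have), ~ !is.na(.x)))
}

#' Shapiro-Wilk normality gate per design cell
#'
#' Screens each (group, segment, region) cell before the comparison stage.
#' The flags are reported alongside, not used to switch tests: the pipeline
#' applies the pre-registered choices (two-way ANOVA for stereology,
#' Kruskal-Wallis for TEM) regardless.
#'
#' @param data tibble of values.
#' @param response column to test (string).
#' @param by grouping columns defining a cell.
#' @param alpha flag threshold.
#' @return tibble: cell columns, `n`, `W`, `p_value`, `flag` in
#'   `normal`/`non_normal`/`untestable`.
#' @export
normality_gate <- function(data, response, by = c("group", "segment", "region"),
                           alpha = 0.05) {
  data <- tibble::as_tibble(data)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise({
      x <- .data[[response]]
      x <- x[!is.na(x)]
      if (length(x) < 3 || length(unique(x)) == 1) {
        tibble::tibble(n = length(x), W = NA_real_, p_value = NA_real_,
                       flag = "untestable")
      } else {
        sw <- shapiro.test(x)
        tibble::tibble(n = length(x), W = unname(sw$statistic),
                       p_value = sw$p.value,
                       flag = ifelse(sw$p.value < alpha, "non_normal", "normal"))
      }
    }, .groups = "drop")
}

#' Percent decrease in a read-out relative to sham, per segment x region
#'
#' For each injured group the sham mean of the same (segment, region) cell
#' is the reference: `100 * (sham - group) / sham`. Negative values are
#' increases. Cells without a sham reference are absent.
#'
#' @param animals per-animal table from [aggregate_to_animal()].
#' @param response estimate column (default vessel density).
#' @param digits rounding of the reported percentage.
#' @return tibble `group, segment, region, sham_mean, group_mean,
#'   percent_decrease`.
#' @export
percent_decrease_map <- function(animals,
                                 response = "vessel_density_per_mm2",
                                 digits = 1) {
  animals <- tibble::as_tibble(animals)
  cell_means <- animals |>
    dplyr::group_by(.data$group, .data$segment, .data$region) |>
    dplyr::summarise(mean_value = mean(.data[[response]], na.rm = TRUE),
                     .groups = "drop")
  sham <- cell_means |>
    dplyr::filter(.data$group == "sham", .data$mean_value > 0) |>
    dplyr::select("segment", "region", sham_mean = "mean_value")
  cell_means |>
    dplyr::filter(.data$group != "sham") |>
    dplyr::inner_join(sham, by = c("segment", "region")) |>
    dplyr::mutate(percent_decrease = round(
      100 * (.data$sham_mean - .data$mean_value) / .data$sham_mean, digits)) |>
    dplyr::select("group", "segment", "region", "sham_mean",
                  group_mean = "mean_value", "percent_decrease")
}

#' White-matter density as a percentage of grey-matter density (sham)
#'
#' `100 * mean(VW, DW) / mean(VG, DG)` over sham animals; with the study's
#' sham means (571, 484, 90, 88 mm^-2) this is 16.9%.
#'
#' @param animals per-animal sham table (non-sham rows are dropped).
#' @param response estimate column.
#' @return percentage, one decimal place.
#' @export
white_grey_ratio <- function(animals, response = "vessel_density_per_mm2") {
  animals <- dplyr::filter(tibble::as_tibble(animals), .data$group == "sham")
  rm <- animals |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(m = mean(.data[[response]], na.rm = TRUE))
  means <- stats::setNames(rm$m, rm$region)
  missing_regions <- setdiff(REGIONS, names(means)[is.finite(means)])
  if (length(missing_regions) > 0)
    abort(paste("missing sham region mean(s):", paste(missing_regions, collapse = ", ")))
  round(100 * mean(means[c("VW", "DW")]) / mean(means[c("VG", "DG")]), 1)
}
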