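# ggplot2 views of the result tables

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of percent decrease vs sham over segment x group
#'
#' @param map output of [percent_decrease_map()].
#' @param region region to display (default: all, facetted).
#' @return a ggplot.
#' @export
plot_decrease_map <- function(map, region = NULL) {
  if (!is.null(region)) map <- dplyr::filter(map, .data$region %in% !!region)
  map$segment <- factor(map$segment, levels = SEGMENTS)
  map$group <- factor(map$group, levels = GROUPS)
  ggplot2::ggplot(map, ggplot2::aes(x = .data$segment, y = .data$group,
                                    fill = .data$percent_decrease)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", .data$percent_decrease)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "% decrease\nvs sham") +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "spinal segment", y = "time point") +
    ggplot2::theme_minimal()
}

#' Per-animal estimates along the cord, by group
#'
#' Trend lines of group means over segments with per-animal points, one
#' panel per region — the spatiotemporal view of a stereological read-out.
#'
#' @param animals per-animal table from [aggregate_to_animal()].
#' @param response estimate column to display.
#' @return a ggplot.
#' @export
plot_segment_profile <- function(animals, response = "vessel_density_per_mm2") {
  animals$segment <- factor(animals$segment, levels = SEGMENTS)
  animals$group <- factor(animals$group, levels = GROUPS)
  ggplot2::ggplot(animals, ggplot2::aes(x = .data$segment,
                                        y = .data[[response]],
                                        colour = .data$group,
                                        group = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "spinal segment", y = response, colour = "group") +
    ggplot2::theme_minimal()
}

#' Bar-and-points view of TEM thickness summaries
#'
#' Group mean +/- SD bars with individual measurements overlaid, one panel
#' per structure x segment.
#'
#' @param measurements thickness-measurement tibble.
#' @return a ggplot.
#' @export
plot_tem_thickness <- function(measurements) {
  summ <- tem_summary(measurements)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean_nm,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_nm - .data$sd_nm,
                                        ymax = .data$mean_nm + .data$sd_nm),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::geom_point(data = measurements,
                        ggplot2::aes(y = .data$thickness_nm),
                        position = ggplot2::position_jitterdodge(
                          jitter.width = 0.15, dodge.width = 0.9),
                        size = 0.4, alpha = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(structure ~ segment, scales = "free_y") +
    ggplot2::labs(x = "group", y = "thickness (nm)") +
    ggplot2::theme_minimal()
}

#' Draw a synthetic vessel scene
#' @param object a [vessel_scene()].
#' @param ... unused.
#' @return a ggplot of the ellipse profiles over the field.
#' @method autoplot vessel_scene
#' @export
autoplot.vessel_scene <- function(object, ...) {
  W <- attr(object, "field_width_um"); H <- attr(object, "field_height_um")
  # ellipse outlines sampled parametrically
  outlines <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    p <- object[i, ]
    t <- seq(0, 2 * pi, length.out = 60)
    u <- p$a_um * cos(t); v <- p$b_um * sin(t)
    tibble::tibble(id = i,
                   x = p$x_um + u * cos(p$theta_rad) - v * sin(p$theta_rad),
                   y = p$y_um + u * sin(p$theta_rad) + v * cos(p$theta_rad))
  })
  ggplot2::ggplot(outlines, ggplot2::aes(.data$x, .data$y, group = .data$id)) +
    ggplot2::geom_polygon(fill = "firebrick", colour = "black",
                          linewidth = 0.2, alpha = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(H, 0), expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
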