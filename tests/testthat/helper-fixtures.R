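# fixtures built in code: analytic traces, simple scenes, toy tables

# closed circular trace of radius r (nm), optionally noisy
circle_trace <- function(r, n = 200, noise_sd = 0, centre = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x_nm = centre[1] + r * cos(t) + rnorm(n, 0, noise_sd),
                 y_nm = centre[2] + r * sin(t) + rnorm(n, 0, noise_sd))
}

ellipse_trace <- function(a, b, n = 400) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x_nm = a * cos(t), y_nm = b * sin(t))
}

# single-disc scene centred in the default field
disc_scene <- function(r = 40, w = 318, h = 429) {
  vessel_scene(tibble::tibble(x_um = w / 2, y_um = h / 2,
                              a_um = r, b_um = r, theta_rad = 0),
               w, h)
}

full_roi <- function(mask) {
  as_mask(matrix(TRUE, nrow(mask), ncol(mask)),
          attr(mask, "pixel_size_um"))
}

# independent perimeter oracle: polygonal arc length of the densely
# sampled parametric ellipse (no elliptic integrals involved)
polygon_perimeter <- function(a, b, n = 20000) {
  t <- seq(0, 2 * pi, length.out = n)
  sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
}

# minimal per-animal table with exact region means
animal_table <- function(means = c(VG = 571, DG = 484, VW = 90, DW = 88),
                         group = "sham", n_animals = 2) {
  tidyr::expand_grid(animal_id = paste0(group, "_a", seq_len(n_animals)),
                     group = group, segment = c("T9", "T10"),
                     region = names(means)) |>
    dplyr::mutate(vessel_density_per_mm2 = unname(means[region]))
}
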