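test_that("cavity rule removes cavity area and flags all-cavity fields", {
  px <- 0.5
  roi <- as_mask(matrix(TRUE, 100, 100), px)
  no_cav <- apply_cavity_rule(roi, NULL)
  expect_equal(no_cav$cavity_fraction, 0)
  expect_false(no_cav$missing)
  expect_equal(sum(no_cav$roi), 100 * 100)

  all_cav <- apply_cavity_rule(roi, roi)
  expect_equal(all_cav$cavity_fraction, 1)
  expect_true(all_cav$missing)

  half <- as_mask(cbind(matrix(TRUE, 100, 50), matrix(FALSE, 100, 50)), px)
  hc <- apply_cavity_rule(roi, half)
  expect_equal(hc$cavity_fraction, 0.5)
  expect_false(hc$missing)
  expect_equal(sum(hc$roi), 100 * 50)
})

test_that("normalisation divides counts by the reference area", {
  counts <- tibble::tibble(points_on_vessel = 10L, intersections_h = 8L,
                           intersections_v = 6L, profile_count = 50L,
                           roi_area_mm2 = 0.1, cavity_fraction = 0,
                           missing = FALSE)
  est <- normalize_field(counts)
  expect_equal(est$vessel_density_per_mm2, 500)
  expect_equal(est$surface_density_um_per_mm2,
               boundary_length(8, 6, 12.25) / 0.1)
  expect_equal(est$areal_density_um2_per_mm2, 10 * 150.0625 / 0.1)
  expect_equal(est$surface_to_volume_per_um,
               est$surface_density_um_per_mm2 / est$areal_density_um2_per_mm2)

  # homogeneity: doubling the area halves densities, leaves S/V unchanged
  est2 <- normalize_field(dplyr::mutate(counts, roi_area_mm2 = 0.2))
  expect_equal(est2$vessel_density_per_mm2, est$vessel_density_per_mm2 / 2)
  expect_equal(est2$surface_density_um_per_mm2, est$surface_density_um_per_mm2 / 2)
  expect_equal(est2$areal_density_um2_per_mm2, est$areal_density_um2_per_mm2 / 2)
  expect_equal(est2$surface_to_volume_per_um, est$surface_to_volume_per_um)
})

test_that("zero reference area without a cavity flag is an error, missing fields stay NA", {
  counts <- tibble::tibble(points_on_vessel = 0L, intersections_h = 0L,
                           intersections_v = 0L, profile_count = 0L,
                           roi_area_mm2 = 0, cavity_fraction = 0,
                           missing = FALSE)
  expect_error(normalize_field(counts), "segmentation failure")
  est <- normalize_field(dplyr::mutate(counts, missing = TRUE))
  expect_true(all(is.na(est$vessel_density_per_mm2)))
  expect_true(all(is.na(est$surface_to_volume_per_um)))
})

test_that("quantify_field recovers exact profile counts and is deterministic", {
  set.seed(5)
  sc <- sample_profiles(300, 160, 160, seed = 8)
  lab <- render_scene(sc, 0.33, labelled = TRUE)
  vm <- as_mask(lab != 0L, 0.33)
  spec <- grid_spec(field_width_um = 160, field_height_um = 160,
                    pixel_size_um = 0.33)
  f1 <- quantify_field(vm, labelled_mask = lab, spec = spec, seed = 3)
  f2 <- quantify_field(vm, labelled_mask = lab, spec = spec, seed = 3)
  expect_identical(f1, f2)
  expect_equal(f1$profile_count, nrow(sc))
  expect_equal(f1$roi_area_mm2, nrow(vm) * ncol(vm) * 0.33^2 / 1e6)
})

test_that("a fully cavitated field yields no estimates, a half cavity rescales the area", {
  sc <- disc_scene(20, 160, 160)
  mask <- render_scene(sc, 0.33)
  roi <- full_roi(mask)
  cav_all <- roi
  f <- quantify_field(mask, roi, cav_all, spec = grid_spec(
    field_width_um = 160, field_height_um = 160, pixel_size_um = 0.33), seed = 1)
  expect_true(f$missing)
  expect_true(is.na(f$vessel_density_per_mm2))

  cav_half <- as_mask(cbind(matrix(TRUE, nrow(mask), floor(ncol(mask) / 2)),
                            matrix(FALSE, nrow(mask), ceiling(ncol(mask) / 2))),
                      0.33)
  f2 <- quantify_field(mask, roi, cav_half, spec = grid_spec(
    field_width_um = 160, field_height_um = 160, pixel_size_um = 0.33), seed = 1)
  expect_false(f2$missing)
  expect_equal(f2$roi_area_mm2,
               (sum(roi) - sum(cav_half)) * 0.33^2 / 1e6)
})
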