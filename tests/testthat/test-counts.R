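test_that("point counting handles empty and saturated masks", {
  px <- 0.33
  empty <- as_mask(matrix(FALSE, 1300, 964), px)
  roi <- full_roi(empty)
  g <- generate_grid(grid_spec(), seed = 1)
  expect_equal(count_points(empty, roi, g)$P, 0)
  full <- as_mask(matrix(TRUE, 1300, 964), px)
  cp <- count_points(full, roi, g)
  expect_equal(cp$P, cp$P_roi)
  expect_error(count_points(full, as_mask(matrix(TRUE, 2, 2), px), g),
               "dimensions")
})

test_that("mean point-count area over offsets matches a disc's area", {
  mask <- render_scene(disc_scene(40), 0.33)
  roi <- full_roi(mask)
  spec <- grid_spec()
  P <- vapply(1:400, function(s)
    count_points(mask, roi, generate_grid(spec, seed = s))$P, numeric(1))
  est <- mean(P) * spec$area_per_point_um2
  expect_lt(abs(est - pi * 40^2) / (pi * 40^2), 0.02)
})

test_that("intersection counts follow the crossing rule", {
  px <- 0.33
  empty <- as_mask(matrix(FALSE, 1300, 964), px)
  roi <- full_roi(empty)
  g0 <- generate_grid(grid_spec(offset_x_um = 0, offset_y_um = 0))
  expect_equal(count_intersections(empty, roi, g0), list(hI = 0L, vI = 0L))

  # 30 um square straddling exactly two lines per family:
  # vertical lines inside (100,130): 110.25, 122.5; horizontal inside
  # (200,230): 208.25, 220.5
  sq <- vessel_scene(tibble::tibble(x_um = 115, y_um = 215, a_um = 15,
                                    b_um = 15, theta_rad = 0))
  m <- matrix(FALSE, 1300, 964)
  xs <- (seq_len(964) - 0.5) * px; ys <- (seq_len(1300) - 0.5) * px
  m[ys >= 200 & ys <= 230, xs >= 100 & xs <= 130] <- TRUE
  m <- as_mask(m, px)
  ints <- count_intersections(m, full_roi(m), g0)
  expect_equal(ints$hI, 4L)
  expect_equal(ints$vI, 4L)
})

test_that("mean boundary length over offsets matches a disc's circumference", {
  mask <- render_scene(disc_scene(40), 0.33)
  roi <- full_roi(mask)
  spec <- grid_spec()
  B <- vapply(1:400, function(s) {
    i <- count_intersections(mask, roi, generate_grid(spec, seed = s))
    boundary_length(i$hI, i$vI, spec$pitch_um)
  }, numeric(1))
  expect_lt(abs(mean(B) - 2 * pi * 40) / (2 * pi * 40), 0.02)
})

test_that("boundary length and point-count area formulas are exact", {
  expect_equal(boundary_length(0, 0), 0)
  expect_equal(boundary_length(10, 10, 12.25), 0.5 * pi * 10 * 12.25)
  expect_error(boundary_length(-1, 0), "non-negative")
  expect_equal(point_count_area(0), 0)
  expect_equal(point_count_area(1, 12.25), 150.0625)
  expect_equal(point_count_area(4, 12.25), 600.25)
  expect_error(point_count_area(-2), "non-negative")
})

test_that("counting frame counts interior profiles once and excludes forbidden-edge hits", {
  px <- 0.5
  lab <- matrix(0L, 200, 200)
  lab[50:60, 50:60] <- 1L
  lab <- as_mask(lab, px)
  expect_equal(count_profiles(lab), 1L)

  # same profile shifted to touch the left image edge
  lab2 <- matrix(0L, 200, 200)
  lab2[50:60, 1:10] <- 1L
  expect_equal(count_profiles(as_mask(lab2, px)), 0L)
  # and the bottom edge
  lab3 <- matrix(0L, 200, 200)
  lab3[195:200, 50:60] <- 1L
  expect_equal(count_profiles(as_mask(lab3, px)), 0L)

  expect_equal(count_profiles(as_mask(matrix(0L, 50, 50), px)), 0L)
  expect_error(count_profiles(as_mask(matrix(FALSE, 5, 5), px)), "labelled")
})

test_that("frame counts of uniformly placed discs match the analytic edge loss", {
  w <- 318; h <- 429; px <- 0.33; r <- 5; n <- 40
  p_keep <- (1 - (r + px / 2) / w) * (1 - (r + px / 2) / h)
  counts <- vapply(1:200, function(s) {
    sc <- sample_profiles(0, w, h, radius_median_um = r, radius_sdlog = 0,
                          tilt_max_rad = 0, placement = "uniform",
                          seed = s, n_profiles = n)
    count_profiles(render_scene(sc, px, labelled = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(counts) - n * p_keep) / (n * p_keep), 0.03)
})
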