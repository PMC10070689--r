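test_that("orthogonal thickness is exact on parallel lines and concentric circles", {
  inner <- tibble::tibble(x_nm = seq(0, 1000, 10), y_nm = 0)
  outer <- tibble::tibble(x_nm = seq(0, 1000, 10), y_nm = 30)
  m <- measure_trace_pair(inner, outer, "intercellular_cleft", n_samples = 4)
  expect_equal(m$thickness_nm, rep(30, 4), tolerance = 1e-9)

  m2 <- measure_trace_pair(circle_trace(500, 400), circle_trace(530, 400),
                           "basement_membrane", n_samples = 8)
  expect_equal(m2$thickness_nm, rep(30, 8), tolerance = 1e-3)
})

test_that("thickness matches a closed-form normal-distance oracle on scaled ellipses", {
  a <- 600; b <- 400; t_in <- ellipse_trace(a, b, 2000)
  # outer curve: the inner ellipse offset by 25 nm along its outward normal
  # (a true parallel curve, so the normal distance is 25 by construction)
  tt <- seq(0, 2 * pi, length.out = 2000)
  nx <- b * cos(tt); ny <- a * sin(tt)
  nl <- sqrt(nx^2 + ny^2)
  t_out <- tibble::tibble(x_nm = a * cos(tt) + 25 * nx / nl,
                          y_nm = b * sin(tt) + 25 * ny / nl)
  m <- measure_trace_pair(t_in, t_out, "basement_membrane", n_samples = 12)
  expect_equal(m$thickness_nm, rep(25, length(m$thickness_nm)),
               tolerance = 0.005)
})

test_that("thickness is invariant under rotation and translation", {
  set.seed(42)
  inner <- circle_trace(500, 300)
  outer <- circle_trace(540, 300)
  base <- measure_trace_pair(inner, outer, "basement_membrane")$thickness_nm
  for (k in 1:3) {
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -1e4, 1e4); dy <- runif(1, -1e4, 1e4)
    rot <- function(tr) tibble::tibble(
      x_nm = tr$x_nm * cos(th) - tr$y_nm * sin(th) + dx,
      y_nm = tr$x_nm * sin(th) + tr$y_nm * cos(th) + dy)
    moved <- measure_trace_pair(rot(inner), rot(outer),
                                "basement_membrane")$thickness_nm
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("noisy annulus thickness is recovered within 5%", {
  set.seed(11)
  inner <- circle_trace(500, 400, noise_sd = 2)
  outer <- circle_trace(534.28, 400, noise_sd = 2)
  m <- measure_trace_pair(inner, outer, "basement_membrane", n_samples = 60)
  expect_gte(length(m$thickness_nm), 50)
  expect_lt(abs(mean(m$thickness_nm) - 34.28) / 34.28, 0.05)
})

test_that("degenerate tangents and missed rays are skipped with a warning", {
  inner <- tibble::tibble(x_nm = c(0, 0, 0, 10, 20), y_nm = c(0, 0, 0, 0, 0))
  outer <- tibble::tibble(x_nm = c(0, 10, 20), y_nm = c(30, 30, 30))
  expect_warning(v <- orthogonal_thickness(inner, outer, 2), "degenerate")
  expect_true(is.na(v))
  # outer far beyond the sanity bound
  far <- tibble::tibble(x_nm = c(0, 10, 20), y_nm = rep(5000, 3))
  expect_warning(v2 <- orthogonal_thickness(
    tibble::tibble(x_nm = c(0, 10, 20), y_nm = 0), far, 2), "misses")
  expect_true(is.na(v2))
})

test_that("minimum-sampling rule excludes under-sampled capillaries only", {
  meas <- tibble::tibble(
    thickness_nm = c(30, 32, 31, 95, 90, 88, 93, 16, 17),
    structure = c(rep("basement_membrane", 7), rep("intercellular_cleft", 2)),
    capillary_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c2", "c3", "c3"),
    segment = "T10", region = "VG", group = "sham", sample_index = 1:9)
  rec <- enforce_sampling(meas)
  expect_false("c1" %in% rec$capillary_id[rec$structure == "basement_membrane"])
  expect_true("c2" %in% rec$capillary_id)
  expect_true("c3" %in% rec$capillary_id)   # 2 cleft measurements suffice

  # exclusion monotonicity: adding measurements never removes a capillary
  more <- dplyr::bind_rows(meas, tibble::tibble(
    thickness_nm = 33, structure = "basement_membrane", capillary_id = "c1",
    segment = "T10", region = "VG", group = "sham", sample_index = 10))
  rec2 <- enforce_sampling(more)
  expect_true(all(rec$capillary_id %in% rec2$capillary_id))
  expect_true("c1" %in% rec2$capillary_id[rec2$structure == "basement_membrane"])
})

test_that("group summaries pool at the requested unit", {
  one <- tibble::tibble(thickness_nm = 16, structure = "intercellular_cleft",
                        capillary_id = "c1", segment = "T10", region = "VG",
                        group = "sham", sample_index = 1)
  s1 <- tem_summary(one)
  expect_equal(s1$mean_nm, 16)
  expect_equal(s1$sd_nm, 0)
  expect_equal(s1$n, 1L)

  # two capillaries with means 10 and 20, equal counts -> grand mean 15
  two <- tibble::tibble(
    thickness_nm = c(9, 11, 19, 21), structure = "intercellular_cleft",
    capillary_id = c("c1", "c1", "c2", "c2"), segment = "T10",
    region = "VG", group = "sham", sample_index = 1:4)
  expect_equal(tem_summary(two, unit = "capillary")$mean_nm, 15)
  expect_equal(tem_summary(two, unit = "measurement")$mean_nm, 15)
})

test_that("recovered group mean from sampled sham clefts is within 1 SE", {
  set.seed(21)
  params <- tibble::tibble(group = "sham", segment = "T10", region = "VG",
                           structure = "intercellular_cleft",
                           mean_nm = 15.52, sd_nm = 3.17, n = 100)
  s <- tem_summary(simulate_tem(params, seed = 5))
  expect_lt(abs(s$mean_nm - 15.52), 3.17 / sqrt(100) * 2)
})

test_that("percent change reproduces the printed cleft increase", {
  expect_equal(percent_change(16.00, 27.28), 70.5)
  expect_equal(percent_change(12, 12), 0)
  expect_equal(percent_change(10, 5), -50)
  expect_error(percent_change(0, 5), "sham_mean")
})
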