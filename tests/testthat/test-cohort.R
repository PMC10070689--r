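make_fields <- function(values_by_section, animal = "a1", group = "sham",
                        segment = "T10", region = "VG") {
  purrr::imap_dfr(values_by_section, function(vals, s)
    tibble::tibble(animal_id = animal, group = group, segment = segment,
                   region = region, section_replicate = s,
                   field_replicate = seq_along(vals),
                   vessel_density_per_mm2 = vals))
}

test_that("aggregation is means of means over sections", {
  same <- make_fields(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)))
  expect_equal(aggregate_to_animal(same)$vessel_density_per_mm2, 5)

  two <- make_fields(list(c(1, 2, 3), c(3, 4, 5)))
  expect_equal(aggregate_to_animal(two)$vessel_density_per_mm2, 3)

  # unequal field counts: sections weighted equally, not fields
  uneq <- make_fields(list(c(0, 0, 0, 0, 0, 0), c(6)))
  expect_equal(aggregate_to_animal(uneq)$vessel_density_per_mm2, 3)
})

test_that("aggregation respects missingness and permutation invariance", {
  f <- make_fields(list(c(2, 4), c(6, 8)))
  with_na <- dplyr::bind_rows(f, tibble::tibble(
    animal_id = "a1", group = "sham", segment = "T10", region = "VG",
    section_replicate = 1L, field_replicate = 3L,
    vessel_density_per_mm2 = NA_real_))
  expect_equal(aggregate_to_animal(with_na)$vessel_density_per_mm2,
               aggregate_to_animal(f)$vessel_density_per_mm2)

  shuffled <- f[sample(nrow(f)), ]
  expect_equal(aggregate_to_animal(shuffled), aggregate_to_animal(f))

  all_na <- dplyr::mutate(f, vessel_density_per_mm2 = NA_real_)
  expect_equal(nrow(aggregate_to_animal(all_na)), 0)
})

test_that("animal means recover the generator's animal effects", {
  design <- default_design()
  design$groups <- "sham"; design$segments <- c("T9", "T10")
  design$regions <- "VG"; design$n_animals <- c(sham = 4)
  model <- effect_model()
  errs <- vapply(1:200, function(s) {
    co <- simulate_cohort(model, design, seed = s)
    an <- aggregate_to_animal(
      dplyr::mutate(co, vessel_density_per_mm2 = density_true_per_mm2))
    truth <- co |>
      dplyr::distinct(animal_id, animal_effect) |>
      dplyr::mutate(expected = 571 * animal_effect)
    j <- dplyr::inner_join(
      dplyr::summarise(dplyr::group_by(an, animal_id),
                       m = mean(vessel_density_per_mm2)),
      truth, by = "animal_id")
    mean(j$m - j$expected)
  }, numeric(1))
  # per-animal mean of 18 Poisson fields at ~78 counts: SE of the cohort
  # mean error ~ sqrt(571/(0.1364*18*4))
  se <- sqrt(571 / (0.136422 * 18 * 4))
  expect_lt(abs(mean(errs)), 2 * se / sqrt(200))
})

test_that("normality gate flags untestable and non-normal cells", {
  const <- tibble::tibble(group = "sham", segment = "T10", region = "VG",
                          vessel_density_per_mm2 = rep(5, 6))
  g1 <- normality_gate(const, "vessel_density_per_mm2")
  expect_equal(g1$flag, "untestable")

  small <- tibble::tibble(group = "d2", segment = "T10", region = "VG",
                          vessel_density_per_mm2 = c(1, 2))
  expect_equal(normality_gate(small, "vessel_density_per_mm2")$flag, "untestable")

  set.seed(30)
  expo <- tibble::tibble(group = "sham", segment = "T10", region = "VG",
                         vessel_density_per_mm2 = stats::rexp(50))
  expect_equal(normality_gate(expo, "vessel_density_per_mm2")$flag, "non_normal")
})

test_that("Shapiro-Wilk gate holds its nominal size on Gaussian cells and has power", {
  set.seed(77)
  rej_norm <- mean(vapply(1:400, function(i) {
    d <- tibble::tibble(group = "sham", segment = "T10", region = "VG",
                        vessel_density_per_mm2 = rnorm(50))
    normality_gate(d, "vessel_density_per_mm2")$flag == "non_normal"
  }, logical(1)))
  expect_gt(rej_norm, 0.02); expect_lt(rej_norm, 0.08)

  rej_exp <- mean(vapply(1:100, function(i) {
    d <- tibble::tibble(group = "sham", segment = "T10", region = "VG",
                        vessel_density_per_mm2 = stats::rexp(50))
    normality_gate(d, "vessel_density_per_mm2")$flag == "non_normal"
  }, logical(1)))
  expect_gt(rej_exp, 0.5)
})

test_that("percent decrease map compares each group cell to its sham mean", {
  an <- dplyr::bind_rows(
    animal_table(c(VG = 571, DG = 484, VW = 90, DW = 88), "sham"),
    animal_table(c(VG = 4.568, DG = 484, VW = 90, DW = 88), "d2"))
  map <- percent_decrease_map(an)
  expect_equal(
    map$percent_decrease[map$group == "d2" & map$segment == "T10" &
                           map$region == "VG"], 99.2)
  expect_equal(
    map$percent_decrease[map$group == "d2" & map$region == "DG"][1], 0)

  # cells without a sham reference are absent
  no_sham <- dplyr::filter(an, !(group == "sham" & region == "VG"))
  map2 <- percent_decrease_map(no_sham)
  expect_false("VG" %in% map2$region)
})

test_that("white/grey sham ratio follows its definition", {
  expect_equal(white_grey_ratio(animal_table()), 16.9)
  expect_equal(white_grey_ratio(
    animal_table(c(VG = 100, DG = 100, VW = 100, DW = 100))), 100)
  expect_equal(white_grey_ratio(
    animal_table(c(VG = 500, DG = 400, VW = 0, DW = 0))), 0)
  expect_error(white_grey_ratio(
    dplyr::filter(animal_table(), region != "DW")), "DW")
})
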