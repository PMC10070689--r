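# spatiotemporal effect model and cohort / TEM simulators

#' Default group x segment x region density multipliers
#'
#' Multipliers relative to sham (1 = no change) for vessel numerical
#' density. Cells follow the study's summary of epicentre and perilesional
#' reductions: at the T10 epicentre on day 2 the ventral and dorsal grey
#' matter fall by 99.2% and 95.3% (multipliers 0.008 and 0.047), with 47/34%
#' (T9) and 75/62% (T11) perilesional reductions; by day 45 the epicentre
#' has recovered to 44% and 49% below sham. Perilesional grey matter
#' returns to under a 25% reduction by day 5. Unlisted cells are 1.
#'
#' @return tibble with columns `group`, `segment`, `region`, `multiplier`.
#' @export
default_multipliers <- function() {
  m <- tibble::tribble(
    ~group, ~segment, ~region, ~multiplier,
    "d2",  "T10", "VG", 0.008,
    "d2",  "T10", "DG", 0.047,
    "d2",  "T9",  "VG", 0.53,
    "d2",  "T9",  "DG", 0.66,
    "d2",  "T11", "VG", 0.25,
    "d2",  "T11", "DG", 0.38,
    "d2",  "T12", "VG", 0.60,
    "d2",  "T12", "DG", 0.65,
    "d2",  "T8",  "VG", 0.80,
    "d2",  "T8",  "DG", 0.80,
    "d2",  "T10", "VW", 0.20,
    "d2",  "T10", "DW", 0.25,
    "d5",  "T9",  "VG", 0.80, "d5",  "T9",  "DG", 0.80,
    "d5",  "T11", "VG", 0.80, "d5",  "T11", "DG", 0.80,
    "d5",  "T10", "VG", 0.30, "d5",  "T10", "DG", 0.35,
    "d5",  "T10", "VW", 0.45, "d5",  "T10", "DW", 0.45,
    "d15", "T10", "VG", 0.45, "d15", "T10", "DG", 0.45,
    "d15", "T9",  "DG", 0.80,
    "d15", "T10", "VW", 0.65, "d15", "T10", "DW", 0.65,
    "d45", "T10", "VG", 0.56, "d45", "T10", "DG", 0.51,
    "d45", "T8",  "DG", 0.71,
    "d45", "T9",  "VW", 1.60)
  m
}

#' Effect model for the synthetic cohort
#'
#' Defines the data-generating process: region baseline densities (sham
#' thoracic means), a multiplicative group x segment x region effect map,
#' a per-animal multiplicative log-normal effect, and the profile geometry
#' (log-normal lumen radius, uniform cut obliquity).
#'
#' @param baseline_density_per_mm2 named vector over regions (mm^-2).
#' @param multipliers tibble as [default_multipliers()]; sham rows are
#'   forced to 1.
#' @param animal_sdlog SD of the log-normal animal effect (0.08 reproduces
#'   cohort SDs near the sham 571 +/- 45 mm^-2 once Poisson field noise is
#'   added).
#' @param radius_median_um,radius_sdlog,tilt_max_rad profile geometry, see
#'   [sample_profiles()].
#' @return an `effect_model` list.
#' @export
effect_model <- function(baseline_density_per_mm2 =
                           c(VG = 571, DG = 484, VW = 90, DW = 88),
                         multipliers = default_multipliers(),
                         animal_sdlog = 0.08,
                         radius_median_um = 4, radius_sdlog = 0.25,
                         tilt_max_rad = pi / 3) {
  stopifnot(all(REGIONS %in% names(baseline_density_per_mm2)),
            all(baseline_density_per_mm2 >= 0),
            all(multipliers$multiplier >= 0))
  check_enum(multipliers$group, GROUPS, "group")
  check_enum(multipliers$segment, SEGMENTS, "segment")
  check_enum(multipliers$region, REGIONS, "region")
  structure(list(baseline = baseline_density_per_mm2,
                 multipliers = dplyr::filter(multipliers, .data$group != "sham"),
                 animal_sdlog = animal_sdlog,
                 radius_median_um = radius_median_um,
                 radius_sdlog = radius_sdlog,
                 tilt_max_rad = tilt_max_rad),
            class = "effect_model")
}

#' Look up the density multiplier for one design cell
#' @param model an [effect_model()].
#' @param group,segment,region design-cell coordinates.
#' @return scalar multiplier (1 where the map has no entry; sham is 1).
#' @export
cell_multiplier <- function(model, group, segment, region) {
  if (group == "sham") return(1)
  hit <- dplyr::filter(model$multipliers, .data$group == !!group,
                       .data$segment == !!segment, .data$region == !!region)
  if (nrow(hit) == 0) 1 else hit$multiplier[[1]]
}

#' Default study design (groups, segments, regions, replication)
#'
#' Four animals per group except day 45 (three); three replicate sections
#' per segment x region, three fields per section.
#' @return list consumed by [simulate_cohort()].
#' @export
default_design <- function() {
  list(groups = GROUPS,
       segments = SEGMENTS,
       regions = REGIONS,
       n_animals = c(sham = 4, d2 = 4, d5 = 4, d15 = 4, d45 = 3),
       n_sections = 3, n_fields = 3,
       field_width_um = 318, field_height_um = 429,
       pixel_size_um = 0.33)
}

design_keys <- function(design) {
  purrr::map_dfr(design$groups, function(g) {
    tidyr::expand_grid(group = g,
                       animal_id = paste0(g, "_a", seq_len(design$n_animals[[g]])),
                       segment = design$segments,
                       region = design$regions,
                       section_replicate = seq_len(design$n_sections),
                       field_replicate = seq_len(design$n_fields))
  })
}

#' Simulate a cohort of vessel fields
#'
#' For every (animal, segment, region, section, field) cell the expected
#' profile count is `baseline * multiplier * animal effect * field area`;
#' the realised count is Poisson. `render = TRUE` builds the actual scenes
#' (and masks on demand via [render_scene()]), which is what end-to-end
#' estimator validation uses; `render = FALSE` returns field-level ground
#' truth only (density realised as N / field area) — the fast path for
#' statistical calibration studies.
#'
#' @param model an [effect_model()].
#' @param design a [default_design()]-shaped list.
#' @param seed master integer seed; every scene gets a deterministic
#'   subseed derived from it and its sample key.
#' @param render build per-field scenes (list-column `scene`).
#' @return tibble: one row per field with the sample key, the expectation
#'   components, ground-truth `n_true`, `density_true_per_mm2`, and
#'   (rendered) the scene.
#' @export
simulate_cohort <- function(model = effect_model(), design = default_design(),
                            seed = 1, render = FALSE) {
  keys <- design_keys(design)
  area_mm2 <- design$field_width_um * design$field_height_um / 1e6
  animals <- dplyr::distinct(keys, .data$group, .data$animal_id)
  animals$animal_effect <- with_seed(subseed(seed, "animals"),
                                     rlnorm(nrow(animals), 0, model$animal_sdlog))
  keys <- dplyr::left_join(keys, animals, by = c("group", "animal_id"))
  keys <- dplyr::left_join(keys, model$multipliers,
                           by = c("group", "segment", "region"))
  keys$multiplier <- dplyr::coalesce(keys$multiplier, 1)
  keys$mean_density <- model$baseline[keys$region] * keys$multiplier * keys$animal_effect
  # deterministic per-field subseed; the 100003 stride keeps the streams of
  # nearby master seeds disjoint for any realistic design size
  keys$field_seed <- as.integer((as.numeric(seed) * 100003 + seq_len(nrow(keys))) %%
                                  2147483647)

  if (render) {
    keys$scene <- purrr::pmap(
      list(keys$mean_density, keys$field_seed),
      function(mu, fs) sample_profiles(
        mu, design$field_width_um, design$field_height_um,
        radius_median_um = model$radius_median_um,
        radius_sdlog = model$radius_sdlog,
        tilt_max_rad = model$tilt_max_rad, seed = fs))
    keys$n_true <- purrr::map_int(keys$scene, nrow)
  } else {
    keys$n_true <- with_seed(subseed(seed, "counts"),
                             rpois(nrow(keys), keys$mean_density * area_mm2))
  }
  keys$density_true_per_mm2 <- keys$n_true / area_mm2
  tibble::as_tibble(keys)
}

#' Quantify the rendered scenes of a simulated cohort
#'
#' Runs [quantify_field()] over every scene (rendering each mask at the
#' design pixel size), returning the tidy per-field estimate table the
#' aggregation stage consumes.
#'
#' @param cohort output of `simulate_cohort(..., render = TRUE)`.
#' @param design the design used to build it.
#' @param spec optional [grid_spec()] (defaults to the standard grid at the
#'   design's field size).
#' @return tibble: sample key + [quantify_field()] columns per field.
#' @export
quantify_cohort <- function(cohort, design = default_design(), spec = NULL) {
  if (!"scene" %in% names(cohort))
    abort("cohort has no scenes; run simulate_cohort(render = TRUE)")
  spec <- spec %||% grid_spec(field_width_um = design$field_width_um,
                              field_height_um = design$field_height_um,
                              pixel_size_um = design$pixel_size_um)
  est <- purrr::map2_dfr(cohort$scene, cohort$field_seed, function(sc, fs) {
    lab <- render_scene(sc, design$pixel_size_um, labelled = TRUE)
    vm <- as_mask(lab != 0L, design$pixel_size_um)
    quantify_field(vm, labelled_mask = lab, spec = spec, seed = fs)
  })
  dplyr::bind_cols(
    dplyr::select(cohort, dplyr::all_of(c(
      "animal_id", "group", "segment", "region",
      "section_replicate", "field_replicate", "n_true"))),
    est)
}

#' Printed thickness summaries used as TEM simulation defaults
#'
#' Group means and SDs (nm) of basement-membrane and intercellular-cleft
#' thickness for sham and day-2 animals at the epicentre (T10) and T11 in
#' ventral/dorsal grey matter; cells without printed values carry
#' representative defaults on the same scale.
#' @return tibble `group, segment, region, structure, mean_nm, sd_nm, n`.
#' @export
tem_default_params <- function() {
  tibble::tribble(
    ~group, ~segment, ~region, ~structure,            ~mean_nm, ~sd_nm, ~n,
    "sham", "T10", "VG", "basement_membrane",   34.28,  6.65, 53,
    "d2",   "T10", "VG", "basement_membrane",   91.08, 24.34, 53,
    "sham", "T10", "DG", "basement_membrane",   29.71,  7.99, 53,
    "d2",   "T10", "DG", "basement_membrane",   71.21, 34.22, 53,
    "sham", "T11", "VG", "basement_membrane",   31.00,  7.00, 53,
    "d2",   "T11", "VG", "basement_membrane",   75.00, 25.00, 53,
    "sham", "T11", "DG", "basement_membrane",   30.00,  7.50, 53,
    "d2",   "T11", "DG", "basement_membrane",   70.00, 26.00, 53,
    "sham", "T10", "VG", "intercellular_cleft", 15.52,  3.17, 33,
    "d2",   "T10", "VG", "intercellular_cleft", 21.91,  5.41, 33,
    "sham", "T10", "DG", "intercellular_cleft", 16.28,  6.71, 33,
    "d2",   "T10", "DG", "intercellular_cleft", 22.69,  7.21, 33,
    "sham", "T11", "DG", "intercellular_cleft", 16.00,  3.29, 33,
    "d2",   "T11", "DG", "intercellular_cleft", 27.28, 11.65, 33,
    "sham", "T11", "VG", "intercellular_cleft", 15.50,  3.20, 33,
    "d2",   "T11", "VG", "intercellular_cleft", 24.00,  8.00, 33)
}

#' Simulate TEM thickness measurements
#'
#' Draws truncated-normal (at zero) thickness samples per design cell and
#' tags them with synthetic capillary IDs such that the minimum-sampling
#' rule (>= 4 basement-membrane, >= 2 cleft measurements per capillary) is
#' satisfied: measurements are dealt to capillaries in blocks of
#' `per_capillary` (default 5 for basement membrane, 3 for clefts).
#'
#' @param params tibble as [tem_default_params()].
#' @param seed integer seed.
#' @param per_capillary named vector of measurements per capillary.
#' @return tibble of thickness measurements (one row per measurement).
#' @export
simulate_tem <- function(params = tem_default_params(), seed = 1,
                         per_capillary = c(basement_membrane = 5,
                                           intercellular_cleft = 3)) {
  stopifnot(all(params$mean_nm > 0), all(params$sd_nm >= 0))
  with_seed(seed, {
    purrr::pmap_dfr(params, function(group, segment, region, structure,
                                     mean_nm, sd_nm, n) {
      x <- rnorm(n, mean_nm, sd_nm)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean_nm, sd_nm)
      k <- per_capillary[[structure]]
      # remainder measurements join the last capillary so every capillary
      # meets the minimum-sampling rule
      idx <- pmin((seq_len(n) - 1) %/% k + 1, max(1, n %/% k))
      cap <- paste0(group, "_", segment, "_", region, "_cap", idx)
      tibble::tibble(thickness_nm = x, structure = structure,
                     capillary_id = cap, segment = segment, region = region,
                     group = group, sample_index = seq_len(n))
    })
  })
}
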