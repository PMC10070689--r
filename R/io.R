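# file formats, manifest validation, configuration and pipeline stages

#' Read a binary or labelled mask from TIFF or PNG
#'
#' Single-channel images; nonzero pixels are foreground. 16-bit TIFFs of
#' integer IDs (written by [write_mask()]) round-trip exactly.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_um physical pixel size to attach.
#' @param labelled decode integer profile IDs instead of a binary mask.
#' @return an [as_mask()] matrix.
#' @export
read_mask <- function(path, pixel_size_um = 0.33, labelled = FALSE) {
  if (!file.exists(path)) abort(paste("mask file not found:", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = {
                  if (!requireNamespace("png", quietly = TRUE))
                    abort("reading PNG masks requires the 'png' package")
                  png::readPNG(path)
                },
                abort(paste("unsupported mask format:", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- if (labelled) matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
       else img != 0
  as_mask(m, pixel_size_um)
}

#' Write a mask to single-channel TIFF
#'
#' Binary masks are written 8-bit 0/1; labelled masks 16-bit with the
#' profile ID stored as ID/65535 (IDs up to 65535).
#'
#' @param mask an [as_mask()] matrix (logical or integer).
#' @param path output `.tif` path.
#' @export
write_mask <- function(mask, path) {
  if (is.logical(mask)) {
    tiff::writeTIFF((mask * 1) + 0, path, bits.per.sample = 8)
  } else {
    if (max(mask) > 65535) abort("labelled mask IDs exceed 16-bit range")
    tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16)
  }
  invisible(path)
}

manifest_key_cols <- c("animal_id", "group", "segment", "region",
                       "section_replicate", "field_replicate")

#' Read and validate a cohort manifest
#'
#' The manifest is the contract between image storage and the pipeline:
#' one row per field with the sample key and the mask file paths. Group,
#' segment and region tokens are validated against the closed study
#' enumerations; duplicate sample keys and missing files are errors.
#'
#' @param path manifest CSV with columns `animal_id, group, segment,
#'   region, section_replicate, field_replicate, vessel_path` and optional
#'   `roi_path, cavity_path, labelled_path, pixel_size_um`.
#' @param check_files verify referenced files exist.
#' @return validated tibble.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  mf <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(manifest_key_cols, "vessel_path")
  miss <- setdiff(need, names(mf))
  if (length(miss) > 0)
    abort(paste("manifest is missing required column(s):", paste(miss, collapse = ", ")))
  check_enum(mf$group, GROUPS, "group")
  check_enum(mf$segment, SEGMENTS, "segment")
  check_enum(mf$region, REGIONS, "region")
  dup <- duplicated(mf[manifest_key_cols])
  if (any(dup))
    abort(paste("duplicate sample key at manifest row(s):",
                paste(which(dup), collapse = ", ")))
  if (check_files) {
    base <- dirname(path)
    for (col in intersect(c("vessel_path", "roi_path", "cavity_path", "labelled_path"),
                          names(mf))) {
      p <- mf[[col]]
      p_abs <- ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(base, p))
      bad <- which(!is.na(p) & p != "" & !file.exists(p_abs))
      if (length(bad) > 0)
        abort(sprintf("manifest row %d: %s '%s' not found", bad[1], col, p[bad[1]]))
      mf[[col]] <- p_abs
    }
  }
  mf
}

#' Read a flat key:value run configuration
#'
#' YAML with flat keys; anything omitted falls back to the defaults of
#' [run_config()].
#'
#' @param path YAML file.
#' @return a run-config list.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Build a run configuration
#'
#' @param out_dir output directory for stage artefacts.
#' @param seed global integer seed; every stage derives subseeds from it.
#' @param pitch_um,field_width_um,field_height_um,pixel_size_um grid and
#'   field geometry (defaults: the study's 12.25 um grid over a
#'   318 x 429 um field at 0.33 um/px).
#' @param cavity_threshold see [apply_cavity_rule()].
#' @param response estimate used by the statistics/report stages.
#' @param groups,segments,regions,n_animals,n_sections,n_fields simulated
#'   design (defaults: a compact two-group demonstration design).
#' @param tem_unit pooling unit for TEM summaries.
#' @param verbose print stage-level progress.
#' @param ... ignored (forward compatibility).
#' @return a `vm_config` list.
#' @export
run_config <- function(out_dir = "vascmorph_out", seed = 1,
                       pitch_um = 12.25, field_width_um = 318,
                       field_height_um = 429, pixel_size_um = 0.33,
                       cavity_threshold = 0.95,
                       response = "vessel_density_per_mm2",
                       groups = c("sham", "d2"),
                       segments = c("T9", "T10", "T11"),
                       regions = "VG",
                       n_animals = 2, n_sections = 2, n_fields = 2,
                       tem_unit = "measurement", verbose = FALSE, ...) {
  na <- if (length(n_animals) == 1)
    stats::setNames(rep(n_animals, length(groups)), groups) else n_animals
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 pitch_um = pitch_um, field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 pixel_size_um = pixel_size_um,
                 cavity_threshold = cavity_threshold, response = response,
                 design = list(groups = groups, segments = segments,
                               regions = regions, n_animals = na,
                               n_sections = n_sections, n_fields = n_fields,
                               field_width_um = field_width_um,
                               field_height_um = field_height_um,
                               pixel_size_um = pixel_size_um),
                 tem_unit = tem_unit, verbose = isTRUE(verbose)),
            class = "vm_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "verbose")])
}

write_stage_table <- function(x, path, config) {
  readr::write_csv(x, path)
  yaml::write_yaml(list(config_hash = config_hash(config),
                        seed = config$seed,
                        version = as.character(utils::packageVersion("vascmorph")),
                        rows = nrow(x)),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

stage_log <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(fmt, ...))
}

#' Run one pipeline stage
#'
#' Stages communicate through tidy CSVs in `config$out_dir`; each table
#' gets a YAML sidecar recording the config hash, seed and package version
#' so deterministic stages can be verified byte-identical on re-run.
#'
#' * `simulate` — synthetic cohort: vessel + labelled masks as TIFF,
#'   `manifest.csv`, `truth.csv`.
#' * `quantify` — per-field counts and estimates -> `fields.csv`.
#' * `aggregate` — per-animal means -> `animals.csv`.
#' * `stats` — normality gate + per-region two-way ANOVA/Tukey ->
#'   `stats.csv`, `normality.csv`.
#' * `report` — percent-decrease map and the bracketed test summaries ->
#'   `percent_decrease_map.csv`, `report.txt`.
#'
#' @param name stage name.
#' @param config a [run_config()].
#' @return invisibly, the paths written.
#' @export
run_stage <- function(name = c("simulate", "quantify", "aggregate",
                               "stats", "report"),
                      config = run_config()) {
  name <- match.arg(name)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(config),
         quantify = stage_quantify(config),
         aggregate = stage_aggregate(config),
         stats = stage_stats(config),
         report = stage_report(config))
}

#' Run every stage in order
#' @param config a [run_config()].
#' @return invisibly, the list of artefact paths by stage.
#' @export
run_pipeline <- function(config = run_config()) {
  res <- lapply(c("simulate", "quantify", "aggregate", "stats", "report"),
                run_stage, config = config)
  invisible(stats::setNames(res, c("simulate", "quantify", "aggregate",
                                   "stats", "report")))
}

stage_simulate <- function(config) {
  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(effect_model(), config$design,
                            seed = config$seed, render = TRUE)
  rows <- seq_len(nrow(cohort))
  vessel_path <- file.path(mask_dir, sprintf("field%04d_vessel.tif", rows))
  labelled_path <- file.path(mask_dir, sprintf("field%04d_label.tif", rows))
  for (i in rows) {
    lab <- render_scene(cohort$scene[[i]], config$pixel_size_um, labelled = TRUE)
    write_mask(as_mask(lab != 0L, config$pixel_size_um), vessel_path[i])
    write_mask(lab, labelled_path[i])
  }
  manifest <- dplyr::bind_cols(
    cohort[manifest_key_cols],
    tibble::tibble(vessel_path = vessel_path, labelled_path = labelled_path,
                   pixel_size_um = config$pixel_size_um))
  truth <- dplyr::select(cohort, dplyr::all_of(manifest_key_cols),
                         "multiplier", "mean_density", "n_true",
                         "density_true_per_mm2")
  p1 <- write_stage_table(manifest, file.path(config$out_dir, "manifest.csv"), config)
  p2 <- write_stage_table(truth, file.path(config$out_dir, "truth.csv"), config)
  stage_log(config, "simulate: %d fields written", nrow(manifest))
  invisible(c(p1, p2))
}

stage_quantify <- function(config) {
  mf <- read_manifest(file.path(config$out_dir, "manifest.csv"))
  if (is.null(mf$pixel_size_um)) abort("manifest has no pixel_size_um column")
  spec <- grid_spec(config$pitch_um, config$field_width_um,
                    config$field_height_um, config$pixel_size_um)
  n_missing <- 0L
  fields <- purrr::map_dfr(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    px <- row$pixel_size_um
    opt_path <- function(col) {
      p <- if (col %in% names(row)) row[[col]] else NA_character_
      if (!is.na(p) && nzchar(p)) p else NULL
    }
    vessel <- read_mask(row$vessel_path, px)
    roi <- if (!is.null(opt_path("roi_path"))) read_mask(opt_path("roi_path"), px)
    cav <- if (!is.null(opt_path("cavity_path"))) read_mask(opt_path("cavity_path"), px)
    lab <- if (!is.null(opt_path("labelled_path")))
      read_mask(opt_path("labelled_path"), px, labelled = TRUE)
    est <- quantify_field(vessel, roi, cav, lab, spec = spec,
                          seed = subseed(config$seed, "grid", i),
                          cavity_threshold = config$cavity_threshold)
    if (est$missing) n_missing <<- n_missing + 1L
    dplyr::bind_cols(row[manifest_key_cols], est)
  })
  stage_log(config, "quantify: %d fields, %d flagged missing (cavity)",
            nrow(fields), n_missing)
  invisible(write_stage_table(fields, file.path(config$out_dir, "fields.csv"), config))
}

stage_aggregate <- function(config) {
  fields <- readr::read_csv(file.path(config$out_dir, "fields.csv"),
                            show_col_types = FALSE)
  animals <- aggregate_to_animal(fields)
  stage_log(config, "aggregate: %d animal-cells", nrow(animals))
  invisible(write_stage_table(animals, file.path(config$out_dir, "animals.csv"), config))
}

stage_stats <- function(config) {
  animals <- readr::read_csv(file.path(config$out_dir, "animals.csv"),
                             show_col_types = FALSE)
  gate <- normality_gate(animals, config$response)
  results <- purrr::map_dfr(unique(animals$region), function(rg) {
    sub <- dplyr::filter(animals, .data$region == rg)
    res <- tryCatch(anova_tukey(sub, config$response), error = function(e) NULL)
    if (is.null(res)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(region = rg), glance(res),
                     tibble::tibble(formatted = format_stat(res)))
  })
  p1 <- write_stage_table(gate, file.path(config$out_dir, "normality.csv"), config)
  p2 <- write_stage_table(results, file.path(config$out_dir, "stats.csv"), config)
  stage_log(config, "stats: %d region tests", nrow(results))
  invisible(c(p1, p2))
}

stage_report <- function(config) {
  animals <- readr::read_csv(file.path(config$out_dir, "animals.csv"),
                             show_col_types = FALSE)
  map <- percent_decrease_map(animals, config$response)
  p1 <- write_stage_table(map, file.path(config$out_dir, "percent_decrease_map.csv"),
                          config)
  stats_path <- file.path(config$out_dir, "stats.csv")
  lines <- c(sprintf("vascmorph report (seed %d, config %s)",
                     config$seed, config_hash(config)), "")
  if (file.exists(stats_path)) {
    st <- readr::read_csv(stats_path, show_col_types = FALSE)
    if (nrow(st) > 0)
      lines <- c(lines, sprintf("%s %s: %s", st$region, config$response,
                                st$formatted))
  }
  lines <- c(lines, "", "percent decrease vs sham:",
             sprintf("  %s %s %s: %.1f%%", map$group, map$segment, map$region,
                     map$percent_decrease))
  rpt <- file.path(config$out_dir, "report.txt")
  writeLines(lines, rpt)
  stage_log(config, "report: %d map cells", nrow(map))
  invisible(c(p1, rpt))
}
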