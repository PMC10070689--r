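# CSV interchange for electron-microscopy contour traces

#' Read contour traces and their manifest, and measure them
#'
#' The trace file holds ordered points, one row per vertex:
#' `pair_id, role (inner|outer), point_order, x_nm, y_nm`. The manifest
#' keys each pair to its biology: `pair_id, structure, capillary_id,
#' segment, region, group`. Every pair is measured with
#' [measure_trace_pair()] at the default equidistant sampling.
#'
#' @param trace_csv path to the trace point CSV.
#' @param manifest_csv path to the pair manifest CSV.
#' @param ... passed to [measure_trace_pair()] (e.g. `n_samples`).
#' @return tidy tibble of thickness measurements.
#' @export
measure_trace_file <- function(trace_csv, manifest_csv, ...) {
  tr <- readr::read_csv(trace_csv, show_col_types = FALSE)
  need <- c("pair_id", "role", "point_order", "x_nm", "y_nm")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    abort(paste("trace file missing column(s):", paste(miss, collapse = ", ")))
  check_enum(tr$role, c("inner", "outer"), "role")
  mf <- readr::read_csv(manifest_csv, show_col_types = FALSE)
  needm <- c("pair_id", "structure", "capillary_id", "segment", "region", "group")
  missm <- setdiff(needm, names(mf))
  if (length(missm) > 0)
    abort(paste("trace manifest missing column(s):", paste(missm, collapse = ", ")))
  check_enum(mf$structure, c("basement_membrane", "intercellular_cleft"), "structure")

  purrr::map_dfr(seq_len(nrow(mf)), function(i) {
    key <- mf[i, ]
    pts <- dplyr::arrange(dplyr::filter(tr, .data$pair_id == key$pair_id),
                          .data$point_order)
    inner <- dplyr::filter(pts, .data$role == "inner")
    outer <- dplyr::filter(pts, .data$role == "outer")
    if (nrow(inner) < 3 || nrow(outer) < 3)
      abort(sprintf("pair '%s': both traces need >= 3 points", key$pair_id))
    measure_trace_pair(inner, outer, structure = key$structure,
                       capillary_id = key$capillary_id, segment = key$segment,
                       region = key$region, group = key$group, ...)
  })
}
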