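#' @importFrom rlang %||% .data abort warn
#' @importFrom stats sd rnorm runif rpois rlnorm median shapiro.test
#'   kruskal.test lm pf p.adjust pnorm quantile complete.cases
#' @importFrom utils head
NULL

# closed enumerations of the study design
GROUPS   <- c("sham", "d2", "d5", "d15", "d45")
SEGMENTS <- paste0("T", 7:13)
REGIONS  <- c("VG", "DG", "VW", "DW")

#' Attach a physical pixel size to a raster mask
#'
#' Masks are plain R matrices: rows index y (origin top-left), columns index
#' x, physical coordinate = (index - 1) * pixel size. Binary masks are
#' logical (or 0/1); labelled masks are integer with 0 = background.
#'
#' @param m matrix.
#' @param pixel_size_um physical edge length of one pixel, micrometres.
#' @return the matrix with a `pixel_size_um` attribute, class `vm_mask`.
#' @export
as_mask <- function(m, pixel_size_um = 0.33) {
  stopifnot(is.matrix(m), is.numeric(pixel_size_um), pixel_size_um > 0)
  attr(m, "pixel_size_um") <- pixel_size_um
  class(m) <- c("vm_mask", class(m))
  m
}

pixel_size <- function(m, default = NULL) {
  ps <- attr(m, "pixel_size_um") %||% default
  if (is.null(ps)) abort("mask has no pixel_size_um attribute and none was supplied")
  ps
}

check_same_raster <- function(a, b, what = c("mask", "mask")) {
  if (!all(dim(a) == dim(b))) {
    abort(sprintf("%s dimensions (%d x %d) do not match %s dimensions (%d x %d)",
                  what[1], nrow(a), ncol(a), what[2], nrow(b), ncol(b)))
  }
  invisible(TRUE)
}

as_logical_mask <- function(m) {
  if (is.logical(m)) m else m != 0
}

check_enum <- function(x, valid, field) {
  bad <- setdiff(unique(as.character(x)), valid)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s) %s; valid tokens are {%s}",
                  field, paste0("'", bad, "'", collapse = ", "),
                  paste(valid, collapse = ",")))
  }
  invisible(TRUE)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic per-unit subseed derived from a master seed (kept < 2^31)
subseed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
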