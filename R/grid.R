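#' Sentinel code for non-terrestrial cells
#'
#' Cells that are ocean, ice, barren, or removed by masking carry this code
#' and are excluded from every statistic.
#' @export
SENTINEL <- -1L

#' One time slice of categorical biome codes on a regular grid
#'
#' @param codes Integer matrix (`n_lat` x `n_lon`), row 1 northernmost.
#'   Non-terrestrial cells carry [SENTINEL] (-1).
#' @param geometry A `grid_geometry` matching `dim(codes)`.
#' @param slice_label Label of the 20-year interval, e.g. `"2000-2020"`;
#'   the start year must be one of 2000, 2020, ..., 2480.
#' @param level `"biome"` (26 classes) or `"megabiome"` (9 classes).
#' @return An object of class `biome_grid` (a list with elements `codes`,
#'   `geometry`, `slice_label`, `level`).
#' @export
biome_grid <- function(codes, geometry, slice_label = "2000-2020",
                       level = c("biome", "megabiome")) {
  level <- match.arg(level)
  stopifnot(inherits(geometry, "grid_geometry"), is.matrix(codes))
  if (!all(dim(codes) == c(geometry$n_lat, geometry$n_lon)))
    stop("codes matrix dimensions do not match geometry")
  storage.mode(codes) <- "integer"
  if (anyNA(codes)) stop("codes must not contain NA; use SENTINEL (-1)")
  parse_slice_label(slice_label)  # validates
  structure(list(codes = codes, geometry = geometry,
                 slice_label = slice_label, level = level),
            class = "biome_grid")
}

#' @export
print.biome_grid <- function(x, ...) {
  n_land <- sum(x$codes != SENTINEL)
  cat(sprintf("biome_grid [%s, %s]: %d x %d cells, %d terrestrial, %d classes\n",
              x$slice_label, x$level, x$geometry$n_lat, x$geometry$n_lon,
              n_land, length(unique(x$codes[x$codes != SENTINEL]))))
  invisible(x)
}

# "2000-2020" (also accepts an en dash) -> c(start, end); start in 2000..2480
parse_slice_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{4})[-–]([0-9]{4})$", label))[[1]]
  if (length(m) != 3)
    stop(sprintf("slice label '%s' is not of the form 'YYYY-YYYY'", label))
  start <- as.integer(m[2]); end <- as.integer(m[3])
  if (!(start %in% seq(2000L, 2480L, 20L)) || end != start + 20L)
    stop(sprintf("slice label '%s' is not a 20-year interval starting in 2000..2480",
                 label))
  c(start = start, end = end)
}

# labels for consecutive slices starting at the baseline interval
slice_labels <- function(n_slices, start = 2000L) {
  starts <- start + 20L * (seq_len(n_slices) - 1L)
  sprintf("%d-%d", starts, starts + 20L)
}

check_aligned <- function(a, b, what = "grids") {
  if (!geometry_equal(a$geometry, b$geometry))
    stop("alignment error: ", what, " have different geometries")
  if (!is.null(a$level) && !is.null(b$level) && a$level != b$level)
    stop("alignment error: ", what, " have different classification levels")
  invisible(TRUE)
}

# area-weighted terrestrial mask helpers: per-cell area matrix for a grid
cell_area_matrix <- function(geometry, areas = build_area_vector(geometry)) {
  matrix(rep(areas, geometry$n_lon), nrow = geometry$n_lat)
}
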