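#' Human-land-use (anthrome) mask
#'
#' A categorical raster of human land-use classes on its own (usually finer)
#' grid. Two masking tiers are defined: the relaxed tier removes only
#' `urban` and `dense settlement`; the stringent tier keeps only `wild` and
#' `semi-natural`. Classes outside the recognized vocabulary are retained at
#' the relaxed tier and removed at the stringent tier (conservative).
#'
#' @param classes Character matrix of class names; `NA` marks
#'   non-terrestrial cells.
#' @param geometry A `grid_geometry` matching `dim(classes)`.
#' @param tier1_removed Classes removed at tier `"urban"`.
#' @param tier2_kept Classes kept at tier `"non_wild"`.
#' @return An object of class `anthrome_mask`.
#' @export
anthrome_mask <- function(classes, geometry,
                          tier1_removed = c("urban", "dense settlement"),
                          tier2_kept = c("wild", "semi-natural")) {
  stopifnot(inherits(geometry, "grid_geometry"), is.matrix(classes))
  if (!all(dim(classes) == c(geometry$n_lat, geometry$n_lon)))
    stop("classes matrix dimensions do not match geometry")
  storage.mode(classes) <- "character"
  structure(list(classes = classes, geometry = geometry,
                 tier1_removed = tier1_removed, tier2_kept = tier2_kept),
            class = "anthrome_mask")
}

#' @export
print.anthrome_mask <- function(x, ...) {
  cat(sprintf("anthrome_mask: %d x %d cells\n", x$geometry$n_lat,
              x$geometry$n_lon))
  print(table(x$classes, useNA = "ifany"))
  invisible(x)
}

# recognized anthrome vocabulary (HYDE-style top-level classes)
ANTHROME_CLASSES <- c("urban", "dense settlement", "cropland", "rangeland",
                      "wild", "semi-natural")

#' Disaggregate a grid to a finer resolution
#'
#' Each parent cell becomes `factor^2` children carrying the parent's code;
#' total area per biome is conserved (the spherical-zone areas of a parent's
#' children sum exactly to the parent's area). `factor = 6` takes the
#' standard 0.5 degree grid to the 1/12 degree anthrome grid.
#'
#' @param grid A `biome_grid`.
#' @param factor Integer refinement factor (>= 1).
#' @return A `biome_grid` at the finer resolution.
#' @export
disaggregate <- function(grid, factor) {
  stopifnot(inherits(grid, "biome_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("disaggregation factor must be >= 1")
  if (factor == 1L) return(grid)
  g <- grid$geometry
  fine <- grid_geometry(
    g$n_lat * factor, g$n_lon * factor,
    g$lat_step / factor, g$lon_step / factor,
    origin = c(g$origin["lat"] + g$lat_step / 2 - g$lat_step / (2 * factor),
               g$origin["lon"] - g$lon_step / 2 + g$lon_step / (2 * factor)),
    radius_km = g$radius_km
  )
  codes <- grid$codes[rep(seq_len(g$n_lat), each = factor),
                      rep(seq_len(g$n_lon), each = factor), drop = FALSE]
  biome_grid(codes, fine, slice_label = grid$slice_label, level = grid$level)
}

#' Remove human-occupied cells from a biome grid
#'
#' Applies an anthrome mask at one of three severities:
#' * `"none"` — the grid is returned unchanged (the unmasked series keeps the
#'   biome model's own land mask);
#' * `"urban"` — cells classed `urban` or `dense settlement` are removed;
#' * `"non_wild"` — every cell not classed `wild` or `semi-natural` is
#'   removed.
#'
#' At the two masking tiers the terrestrial domain is the intersection of the
#' grid's and the mask's land cells: a cell non-terrestrial in either becomes
#' sentinel. The mask is static in time by design; call [disaggregate()]
#' first so grid and mask share a geometry (origins must agree to within half
#' a cell, which is snapped; larger offsets are an error, never resampled).
#'
#' @param grid A `biome_grid`.
#' @param mask An `anthrome_mask` on the same geometry.
#' @param tier One of `"none"`, `"urban"`, `"non_wild"`.
#' @return A `biome_grid` with masked cells set to [SENTINEL].
#' @export
apply_mask <- function(grid, mask, tier = c("none", "urban", "non_wild")) {
  tier <- match.arg(tier)
  if (tier == "none") return(grid)
  stopifnot(inherits(grid, "biome_grid"), inherits(mask, "anthrome_mask"))
  ga <- grid$geometry; gb <- mask$geometry
  if (ga$n_lat != gb$n_lat || ga$n_lon != gb$n_lon ||
      abs(ga$lat_step - gb$lat_step) > 1e-9 ||
      abs(ga$lon_step - gb$lon_step) > 1e-9)
    stop("alignment error: grid and mask shapes differ; disaggregate first")
  if (abs(ga$origin["lat"] - gb$origin["lat"]) > ga$lat_step / 2 ||
      abs(normalize_lon(ga$origin["lon"] - gb$origin["lon"])) > ga$lon_step / 2)
    stop("alignment error: grid and mask origins differ by more than half a cell")
  cls <- mask$classes
  unknown <- !is.na(cls) & !(cls %in% ANTHROME_CLASSES)
  if (any(unknown))
    message(sum(unknown), " cells carry unrecognized anthrome classes ",
            "(kept at tier 'urban', removed at tier 'non_wild')")
  removed <- if (tier == "urban") {
    !is.na(cls) & cls %in% mask$tier1_removed
  } else {
    !(!is.na(cls) & cls %in% mask$tier2_kept)
  }
  codes <- grid$codes
  codes[removed | is.na(cls)] <- SENTINEL
  biome_grid(codes, grid$geometry, slice_label = grid$slice_label,
             level = grid$level)
}
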