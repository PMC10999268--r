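#' Area-weighted fraction of terrestrial area changing class
#'
#' Compares the class of every cell between a slice and a reference slice
#' (the previous slice, or the present-day baseline) and returns the changed
#' area as a fraction of terrestrial area, globally and within the low
#' (|lat| < 30), mid (30-60) and high (60-90) latitude bands. Cells sentinel
#' in either grid are excluded from numerator and denominator, so fractions
#' are proportions of the area terrestrial in both slices.
#'
#' @param grid_t,grid_ref Aligned `biome_grid`s at the same level.
#' @param areas Per-row areas from [build_area_vector()]; defaults to the
#'   grid's own geometry.
#' @return A data.frame with one row per scope (`global`, `low`, `mid`,
#'   `high`): `changed_km2`, `terrestrial_km2`, `fraction`. Band changed
#'   areas sum exactly to the global changed area.
#' @export
change_fraction <- function(grid_t, grid_ref,
                            areas = build_area_vector(grid_t$geometry)) {
  check_aligned(grid_t, grid_ref)
  g <- grid_t$geometry
  live <- grid_t$codes != SENTINEL & grid_ref$codes != SENTINEL
  changed <- live & (grid_t$codes != grid_ref$codes)
  w <- cell_area_matrix(g, areas)
  band <- lat_band(row_lats(g))[row(live)]
  scope_stats <- function(sel) {
    tot <- sum(w[live & sel])
    chg <- sum(w[changed & sel])
    c(chg, tot, if (tot > 0) chg / tot else NA_real_)
  }
  rows <- rbind(
    global = scope_stats(TRUE),
    low    = scope_stats(band == "low"),
    mid    = scope_stats(band == "mid"),
    high   = scope_stats(band == "high")
  )
  data.frame(scope = rownames(rows), changed_km2 = rows[, 1],
             terrestrial_km2 = rows[, 2], fraction = rows[, 3],
             row.names = NULL)
}

#' Total climatically suitable area per biome
#'
#' @param grid A `biome_grid`.
#' @param areas Per-row areas from [build_area_vector()].
#' @return A data.frame with one row per code present in the grid: `code`,
#'   `area_km2`, sorted by code. Summing `area_km2` gives the grid's total
#'   terrestrial area. An all-sentinel grid yields zero rows.
#' @export
area_by_biome <- function(grid, areas = build_area_vector(grid$geometry)) {
  stopifnot(inherits(grid, "biome_grid"))
  live <- grid$codes != SENTINEL
  if (!any(live))
    return(data.frame(code = integer(), area_km2 = numeric()))
  w <- cell_area_matrix(grid$geometry, areas)
  tab <- tapply(w[live], grid$codes[live], sum)
  data.frame(code = as.integer(names(tab)), area_km2 = as.numeric(tab),
             row.names = NULL)
}
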