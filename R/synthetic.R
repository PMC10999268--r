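# smooth a white-noise field with a (2k+1)-cell moving-average kernel;
# columns wrap (global longitudes), rows do not. Returns a field rescaled to
# zero mean, unit sd.
smooth_noise <- function(n_lat, n_lon, corr_len) {
  z <- matrix(stats::rnorm(n_lat * n_lon), n_lat, n_lon)
  k <- max(0L, as.integer(round(corr_len)))
  if (k > 0) {
    acc <- matrix(0, n_lat, n_lon)
    for (dr in -k:k) for (dc in -k:k) {
      src_r <- pmin(pmax(seq_len(n_lat) - dr, 1L), n_lat)   # clamp at poles
      src_c <- ((seq_len(n_lon) - dc - 1L) %% n_lon) + 1L   # wrap lon
      acc <- acc + z[src_r, src_c, drop = FALSE]
    }
    z <- acc
  }
  (z - mean(z)) / stats::sd(z)
}

#' Specification of a synthetic biome-change scenario
#'
#' Describes a seeded random world with the statistical structure the change
#' and migration metrics consume: zonally banded biomes (climate zonation),
#' a per-slice probability that a terrestrial cell is forced toward another
#' biome, a steady northward drift of zone boundaries, spatially correlated
#' boundary noise (patchiness), and an ocean fraction.
#'
#' @param geometry A `grid_geometry`.
#' @param n_slices Number of 20-year slices (default 25: 2000-2500).
#' @param zonal_layout Ordered biome codes from the northernmost to the
#'   southernmost latitude band. The default is an equator-symmetric
#'   tundra / boreal / temperate / grassland / desert / tropical sequence.
#' @param per_slice_change_rate Probability in `[0, 1]` that a terrestrial
#'   cell switches biome between adjacent slices (default 0.12, the rate of
#'   near-term change per 20 years the metrics are designed to detect).
#' @param drift_deg_per_slice Northward displacement of zone boundaries per
#'   slice, degrees (default 0).
#' @param patchiness Spatial correlation length of boundary noise, in cells
#'   (default 2).
#' @param boundary_jitter_deg Amplitude of the correlated boundary noise in
#'   degrees of latitude (default 1.5).
#' @param ocean_fraction Fraction of cells marked non-terrestrial
#'   (default 0.3).
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(geometry, n_slices = 25,
                          zonal_layout = c(24L, 10L, 7L, 20L, 21L, 1L,
                                           21L, 20L, 7L, 10L, 24L),
                          per_slice_change_rate = 0.12,
                          drift_deg_per_slice = 0,
                          patchiness = 2,
                          boundary_jitter_deg = 1.5,
                          ocean_fraction = 0.3,
                          seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (n_slices < 2) stop("scenario needs at least 2 slices")
  if (per_slice_change_rate < 0 || per_slice_change_rate > 1)
    stop("per_slice_change_rate must be in [0, 1]")
  if (ocean_fraction < 0 || ocean_fraction >= 1)
    stop("ocean_fraction must be in [0, 1)")
  if (patchiness < 0 || boundary_jitter_deg < 0)
    stop("patchiness and boundary_jitter_deg must be non-negative")
  zonal_layout <- as.integer(zonal_layout)
  if (length(zonal_layout) < 1 || anyNA(zonal_layout))
    stop("zonal_layout must be a non-empty vector of biome codes")
  if (length(unique(zonal_layout)) > 26)
    stop("zonal_layout uses more codes than the scheme has biomes")
  structure(list(geometry = geometry, n_slices = as.integer(n_slices),
                 zonal_layout = zonal_layout,
                 per_slice_change_rate = per_slice_change_rate,
                 drift_deg_per_slice = drift_deg_per_slice,
                 patchiness = patchiness,
                 boundary_jitter_deg = boundary_jitter_deg,
                 ocean_fraction = ocean_fraction, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a synthetic biome time series
#'
#' Slice 1 assigns each terrestrial cell the biome of its latitude band,
#' with band boundaries perturbed by spatially correlated noise so zones are
#' patchy rather than ruler-straight. Each later slice is the previous one
#' with (i) zone boundaries displaced northward by `drift_deg_per_slice`
#' and (ii) independent per-cell switches with probability
#' `per_slice_change_rate`; a switching cell takes the biome of a
#' neighbouring latitude band (guaranteed different from its current code),
#' so synthetic change resembles climatic forcing rather than uniform
#' noise. The land/ocean mask is fixed across slices. Identical seeds give
#' identical output.
#'
#' @param spec A `scenario_spec`.
#' @return A list of `n_slices` `biome_grid`s labelled "2000-2020",
#'   "2020-2040", ...
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  g <- spec$geometry
  set.seed(spec$seed)
  jitter <- spec$boundary_jitter_deg *
    smooth_noise(g$n_lat, g$n_lon, spec$patchiness)
  ocean_field <- smooth_noise(g$n_lat, g$n_lon, spec$patchiness)
  ocean <- ocean_field < stats::quantile(ocean_field, spec$ocean_fraction)

  lat0 <- matrix(rep(row_lats(g), g$n_lon), g$n_lat) + jitter
  lat_span <- range(row_lats(g)) + c(-g$lat_step, g$lat_step) / 2
  nb <- length(spec$zonal_layout)
  # band 1 = northernmost; boundaries equally spaced across the grid's span
  band_of <- function(lat_eff) {
    brk <- seq(lat_span[2], lat_span[1], length.out = nb + 1)[-c(1, nb + 1)]
    idx <- matrix(1L, nrow(lat_eff), ncol(lat_eff))
    for (b in brk) idx <- idx + (lat_eff < b)
    idx
  }
  labels <- slice_labels(spec$n_slices)
  grids <- vector("list", spec$n_slices)

  band_prev <- band_of(lat0)
  codes <- matrix(spec$zonal_layout[band_prev], g$n_lat, g$n_lon)
  codes[ocean] <- SENTINEL
  grids[[1]] <- biome_grid(codes, g, slice_label = labels[1])

  for (t in seq_len(spec$n_slices - 1L)) {
    band_t <- band_of(lat0 - t * spec$drift_deg_per_slice)
    codes[!ocean & band_t != band_prev] <-
      spec$zonal_layout[band_t[!ocean & band_t != band_prev]]
    band_prev <- band_t
    # independent per-cell climatic switches toward a neighbouring band
    hit <- !ocean & stats::runif(g$n_lat * g$n_lon) < spec$per_slice_change_rate
    if (any(hit)) {
      bd <- band_t[hit]
      side <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
      nb1 <- pmin(pmax(bd + side, 1L), nb)
      nb2 <- pmin(pmax(bd - side, 1L), nb)
      cur <- codes[hit]
      cand <- spec$zonal_layout[nb1]
      alt <- spec$zonal_layout[nb2]
      cand[cand == cur] <- alt[cand == cur]
      # final fallback: any layout code different from the current one
      still <- cand == cur
      if (any(still)) {
        pool <- unique(spec$zonal_layout)
        if (length(pool) > 1)
          cand[still] <- vapply(cur[still], function(cc)
            sample(pool[pool != cc], 1L), integer(1))
      }
      codes[hit] <- cand
    }
    grids[[t + 1L]] <- biome_grid(codes, g, slice_label = labels[t + 1L])
  }
  grids
}

#' Specification of a synthetic anthrome mask
#'
#' @param geometry A `grid_geometry`, typically at 1/12 degree.
#' @param class_fractions Named numeric vector of target area fractions over
#'   the anthrome vocabulary (`urban`, `dense settlement`, `cropland`,
#'   `rangeland`, `wild`, `semi-natural`); must sum to 1. The default is a
#'   rough present-day global mix: mostly wild/semi-natural land with
#'   substantial agriculture and a small settled footprint.
#' @param clustering Spatial correlation length in cells (default 3).
#' @param seed Integer RNG seed.
#' @return An object of class `anthrome_spec`.
#' @export
anthrome_spec <- function(geometry,
                          class_fractions = c("urban" = 0.01,
                                              "dense settlement" = 0.02,
                                              "cropland" = 0.13,
                                              "rangeland" = 0.30,
                                              "semi-natural" = 0.30,
                                              "wild" = 0.24),
                          clustering = 3, seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.null(names(class_fractions)) || any(!nzchar(names(class_fractions))))
    stop("class_fractions must be named")
  if (any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be non-negative and sum to 1")
  structure(list(geometry = geometry, class_fractions = class_fractions,
                 clustering = clustering, seed = as.integer(seed)),
            class = "anthrome_spec")
}

#' Generate a synthetic anthrome mask
#'
#' A spatially correlated Gaussian field is quantile-sliced into the
#' requested classes, producing clustered (multi-cell) patches whose
#' realized cell fractions match the requested fractions to within rounding.
#' Reproducible under a fixed seed.
#'
#' @param spec An `anthrome_spec`.
#' @return An `anthrome_mask` on `spec$geometry`.
#' @export
make_anthromes <- function(spec) {
  stopifnot(inherits(spec, "anthrome_spec"))
  g <- spec$geometry
  set.seed(spec$seed)
  z <- smooth_noise(g$n_lat, g$n_lon, spec$clustering)
  q <- stats::quantile(z, cumsum(spec$class_fractions))
  q[length(q)] <- Inf
  cls <- matrix(names(spec$class_fractions)[
    findInterval(z, c(-Inf, q[-length(q)]))], g$n_lat, g$n_lon)
  anthrome_mask(cls, g)
}
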