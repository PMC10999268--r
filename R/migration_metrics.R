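# shift a logical matrix by (dr, dc); rows never wrap (poles), columns wrap
# across the antimeridian when wrap = TRUE
shift_mask <- function(m, dr, dc, wrap) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dr
  keep_r <- src_r >= 1 & src_r <= nr
  if (!any(keep_r)) return(out)
  if (wrap) {
    src_c <- ((seq_len(nc) - dc - 1) %% nc) + 1
    out[keep_r, ] <- m[src_r[keep_r], src_c, drop = FALSE]
  } else {
    src_c <- seq_len(nc) - dc
    keep_c <- src_c >= 1 & src_c <= nc
    if (any(keep_c))
      out[keep_r, keep_c] <- m[src_r[keep_r], src_c[keep_c], drop = FALSE]
  }
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else stop("connectivity must be 4 or 8")
}

# mask of cells that are TRUE or have a TRUE neighbour
dilate_mask <- function(m, connectivity, wrap) {
  out <- m
  for (off in neighbour_offsets(connectivity))
    out <- out | shift_mask(m, off[1], off[2], wrap)
  out
}

#' Proportion of a biome's area overlapping its previous distribution
#'
#' For every biome present at time t, the fraction of its climatically
#' suitable area lying in cells that were suitable for the same biome in the
#' reference slice. One minus this value is the proportion of area whose
#' realization would require colonizing new ground.
#'
#' @param grid_t,grid_prev Aligned `biome_grid`s at the same level.
#' @param areas Per-row areas from [build_area_vector()].
#' @return A data.frame, one row per code present at t: `code`, `area_km2`
#'   (area at t), `overlap` in `[0, 1]`. A biome absent from the reference
#'   slice gets 0.
#' @export
overlap_proportion <- function(grid_t, grid_prev,
                               areas = build_area_vector(grid_t$geometry)) {
  check_aligned(grid_t, grid_prev)
  w <- cell_area_matrix(grid_t$geometry, areas)
  codes <- sort(unique(grid_t$codes[grid_t$codes != SENTINEL]))
  res <- lapply(codes, function(b) {
    at_t <- grid_t$codes == b
    tot <- sum(w[at_t])
    ov <- sum(w[at_t & grid_prev$codes == b])
    data.frame(code = b, area_km2 = tot, overlap = ov / tot)
  })
  if (!length(res))
    return(data.frame(code = integer(), area_km2 = numeric(),
                      overlap = numeric()))
  do.call(rbind, res)
}

#' Fraction of a biome's area requiring long-distance migration
#'
#' The fraction of biome b's area at time t lying in cells that neither
#' carried b in the previous slice nor touch (under the chosen connectivity,
#' optionally wrapping the antimeridian) any cell that did. Such area could
#' only be realized by long-distance dispersal or transplantation. A cell
#' that itself carried b previously counts as adjacent.
#'
#' @inheritParams overlap_proportion
#' @param connectivity 4 (rook) or 8 (queen) neighbourhood.
#' @param wrap Treat columns 1 and n_lon as adjacent (default TRUE).
#' @return A data.frame, one row per code present at t: `code`, `area_km2`,
#'   `non_adjacent` in `[0, 1]`. Always `<= 1 - overlap` for the same pair.
#' @export
non_adjacent_fraction <- function(grid_t, grid_prev,
                                  areas = build_area_vector(grid_t$geometry),
                                  connectivity = 8, wrap = TRUE) {
  check_aligned(grid_t, grid_prev)
  w <- cell_area_matrix(grid_t$geometry, areas)
  codes <- sort(unique(grid_t$codes[grid_t$codes != SENTINEL]))
  res <- lapply(codes, function(b) {
    at_t <- grid_t$codes == b
    near_prev <- dilate_mask(grid_prev$codes == b, connectivity, wrap)
    tot <- sum(w[at_t])
    far <- sum(w[at_t & !near_prev])
    data.frame(code = b, area_km2 = tot, non_adjacent = far / tot)
  })
  if (!length(res))
    return(data.frame(code = integer(), area_km2 = numeric(),
                      non_adjacent = numeric()))
  do.call(rbind, res)
}

#' Connected-component patches of every biome
#'
#' Labels maximal connected sets of same-code cells (patches — spatially
#' segregated areas suited to a biome). With `wrap = TRUE`, the first and
#' last columns are adjacent so patches may span the antimeridian. Rows never
#' wrap across the poles.
#'
#' @param grid A `biome_grid`.
#' @param connectivity 4 or 8.
#' @param wrap Wrap longitudes (default TRUE).
#' @return A list of class `patch_labeling`: `counts` (named integer vector,
#'   patches per code; every present code has >= 1), `labels` (integer matrix
#'   of patch ids, 0 on sentinel cells), `connectivity`, `wrap`.
#' @export
label_patches <- function(grid, connectivity = 8, wrap = TRUE) {
  stopifnot(inherits(grid, "biome_grid"))
  codes <- grid$codes
  nr <- nrow(codes); nc <- ncol(codes)
  id <- matrix(seq_len(nr * nc), nr, nc)
  live <- codes != SENTINEL

  edge_from <- integer(0); edge_to <- integer(0)
  add_edges <- function(a, b) {
    ok <- live[a] & live[b] & codes[a] == codes[b]
    edge_from <<- c(edge_from, a[ok]); edge_to <<- c(edge_to, b[ok])
  }
  if (nc > 1) add_edges(id[, -nc], id[, -1])                 # east
  if (nr > 1) add_edges(id[-nr, ], id[-1, ])                 # south
  if (wrap && nc > 2) add_edges(id[, nc], id[, 1])           # antimeridian
  if (connectivity == 8) {
    if (nr > 1 && nc > 1) {
      add_edges(id[-nr, -nc], id[-1, -1])                    # south-east
      add_edges(id[-nr, -1], id[-1, -nc])                    # south-west
    }
    if (wrap && nr > 1 && nc > 2) {
      add_edges(id[-nr, nc], id[-1, 1])
      add_edges(id[-1, nc], id[-nr, 1])
    }
  } else if (connectivity != 4) stop("connectivity must be 4 or 8")

  g <- igraph::graph_from_edgelist(cbind(edge_from, edge_to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nr * nc - igraph::vcount(g)))
  memb <- igraph::components(g)$membership

  labels <- matrix(0L, nr, nc)
  if (any(live)) {
    m <- memb[id[live]]
    labels[live] <- match(m, unique(m[order(id[live])]))
  }
  present <- sort(unique(codes[live]))
  counts <- vapply(present, function(b)
    length(unique(labels[codes == b])), integer(1))
  structure(list(counts = stats::setNames(counts, present), labels = labels,
                 connectivity = connectivity, wrap = wrap),
            class = "patch_labeling")
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf("patch_labeling (connectivity %d, wrap %s):\n", x$connectivity,
              x$wrap))
  print(x$counts)
  invisible(x)
}

#' Area-weighted centroid of a biome's distribution
#'
#' Cell centres are mapped to unit vectors in 3-D, averaged with cell-area
#' weights, and the mean vector is projected back to the sphere. This avoids
#' the antimeridian and high-latitude artifacts of naive lat/lon averaging.
#'
#' @param grid A `biome_grid`.
#' @param biome Integer code of the biome.
#' @param areas Per-row areas from [build_area_vector()].
#' @return Named numeric `c(lat, lon)` in degrees, `lon` in `[-180, 180)`.
#'   Errors if the biome is absent, or if the distribution is antipodally
#'   balanced (mean vector norm < 1e-9) so no centroid is defined.
#' @export
biome_centroid <- function(grid, biome,
                           areas = build_area_vector(grid$geometry)) {
  stopifnot(inherits(grid, "biome_grid"))
  sel <- grid$codes == biome & grid$codes != SENTINEL
  if (!any(sel)) stop("biome ", biome, " absent from grid")
  d2r <- pi / 180
  lat <- row_lats(grid$geometry)[row(sel)[sel]] * d2r
  lon <- col_lons(grid$geometry)[col(sel)[sel]] * d2r
  w <- cell_area_matrix(grid$geometry, areas)[sel]
  v <- c(sum(w * cos(lat) * cos(lon)),
         sum(w * cos(lat) * sin(lon)),
         sum(w * sin(lat))) / sum(w)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9)
    stop("degenerate centroid: biome ", biome,
         " is antipodally balanced (mean vector norm < 1e-9)")
  v <- v / nv
  c(lat = asin(v[3]) / d2r, lon = normalize_lon(atan2(v[2], v[1]) / d2r))
}

#' Great-circle step between two centroids
#'
#' Haversine distance and initial bearing (degrees clockwise from north)
#' from `c_prev` toward `c_t`. Coincident points return distance 0 and
#' bearing 0 by convention.
#'
#' @param c_prev,c_t Numeric `(lat, lon)` pairs in degrees.
#' @param radius_km Sphere radius in km.
#' @return Named numeric `c(distance_km, bearing_deg)`; bearing in
#'   `[0, 360)`.
#' @examples
#' centroid_step(c(0, 0), c(0, 1))  # ~111.19 km due east
#' @export
centroid_step <- function(c_prev, c_t, radius_km = 6371.0) {
  d2r <- pi / 180
  phi1 <- c_prev[1] * d2r; phi2 <- c_t[1] * d2r
  dphi <- (c_t[1] - c_prev[1]) * d2r
  dlam <- normalize_lon(c_t[2] - c_prev[2]) * d2r
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  dist <- 2 * radius_km * asin(pmin(1, sqrt(a)))
  if (dist == 0) return(c(distance_km = 0, bearing_deg = 0))
  theta <- atan2(sin(dlam) * cos(phi2),
                 cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam))
  c(distance_km = unname(dist),
    bearing_deg = unname((theta / d2r) %% 360))
}

#' Centroid track of every biome across a time series
#'
#' @param grids List of aligned `biome_grid`s in time order.
#' @param areas Per-row areas (defaults to the first grid's geometry).
#' @param min_step_km Steps shorter than this are flagged low-confidence
#'   (bearing is numerically unstable for tiny displacements).
#' @return A data.frame with one row per (code, slice): `code`,
#'   `slice_label`, `lat`, `lon`, `step_km`, `bearing_deg`,
#'   `low_confidence`. Slices where a biome is absent appear with NA
#'   coordinates (a gap); steps are only computed between consecutive
#'   presences in adjacent slices.
#' @export
centroid_track <- function(grids,
                           areas = build_area_vector(grids[[1]]$geometry),
                           min_step_km = 1) {
  stopifnot(length(grids) >= 1)
  for (g in grids[-1]) check_aligned(grids[[1]], g)
  radius <- grids[[1]]$geometry$radius_km
  codes <- sort(unique(unlist(lapply(grids, function(g)
    g$codes[g$codes != SENTINEL]))))
  rows <- list()
  for (b in codes) {
    prev <- NULL
    for (i in seq_along(grids)) {
      g <- grids[[i]]
      present <- any(g$codes == b)
      if (!present) {
        rows[[length(rows) + 1]] <- data.frame(
          code = b, slice_label = g$slice_label, lat = NA_real_,
          lon = NA_real_, step_km = NA_real_, bearing_deg = NA_real_,
          low_confidence = NA)
        prev <- NULL
        next
      }
      ct <- biome_centroid(g, b, areas)
      if (is.null(prev)) {
        step <- c(distance_km = NA_real_, bearing_deg = NA_real_)
      } else {
        step <- centroid_step(prev, ct, radius)
      }
      rows[[length(rows) + 1]] <- data.frame(
        code = b, slice_label = g$slice_label,
        lat = unname(ct["lat"]), lon = unname(ct["lon"]),
        step_km = unname(step["distance_km"]),
        bearing_deg = unname(step["bearing_deg"]),
        low_confidence = !is.na(step["distance_km"]) &&
          step["distance_km"] < min_step_km)
      prev <- ct
    }
  }
  do.call(rbind, rows)
}
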