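# Independent oracles and toy-fixture builders. These deliberately avoid the
# package's own code paths (shifting/igraph/analytic areas) so they can act
# as references.

# brute-force recursive flood fill; returns per-code patch counts
oracle_patch_counts <- function(codes, connectivity, wrap) {
  nr <- nrow(codes); nc <- ncol(codes)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand_offs <- expand.grid(dr = -1:1, dc = -1:1)
    expand_offs <- expand_offs[!(expand_offs$dr == 0 & expand_offs$dc == 0), ]
    split(as.matrix(expand_offs), seq_len(nrow(expand_offs)))
  }
  seen <- matrix(FALSE, nr, nc)
  fill <- function(r, c, code) {
    seen[r, c] <<- TRUE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr) next
      if (wrap) cc <- ((cc - 1) %% nc) + 1
      if (cc < 1 || cc > nc) next
      if (!seen[rr, cc] && codes[rr, cc] == code) fill(rr, cc, code)
    }
  }
  counts <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    code <- codes[r, c]
    if (code == biomeshift::SENTINEL || seen[r, c]) next
    counts[as.character(code)] <- sum(counts[as.character(code)], 1L,
                                      na.rm = TRUE)
    fill(r, c, code)
  }
  counts[order(as.integer(names(counts)))]
}

# midpoint-rule quadrature of R^2 cos(phi) over a cell (independent of the
# closed-form zone formula)
oracle_cell_area <- function(lat_south, lat_north, lon_step,
                             radius_km = 6371, n_sub = 1e4) {
  d2r <- pi / 180
  h <- (lat_north - lat_south) / n_sub
  mid <- lat_south + (seq_len(n_sub) - 0.5) * h
  radius_km^2 * (lon_step * d2r) * sum(cos(mid * d2r)) * (h * d2r)
}

# haversine distance written straight from the formula
oracle_haversine <- function(p1, p2, radius_km = 6371) {
  d2r <- pi / 180
  dphi <- (p2[1] - p1[1]) * d2r; dlam <- (p2[2] - p1[2]) * d2r
  a <- sin(dphi / 2)^2 + cos(p1[1] * d2r) * cos(p2[1] * d2r) * sin(dlam / 2)^2
  2 * radius_km * asin(sqrt(a))
}

# small grid centred on the equator so toy examples are easy to reason about
toy_geom <- function(n_lat = 1, n_lon = 4, step = 1) {
  biomeshift::grid_geometry(n_lat, n_lon, step, step,
                            origin = c((n_lat - 1) * step / 2,
                                       -((n_lon - 1) * step / 2)))
}

toy_grid <- function(codes, step = 1, level = "biome") {
  codes <- as.matrix(codes)
  biomeshift::biome_grid(codes, toy_geom(nrow(codes), ncol(codes), step),
                         level = level)
}

random_codes <- function(nr, nc, codes = 1:3, p_sentinel = 0.2) {
  m <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  m[matrix(runif(nr * nc) < p_sentinel, nr, nc)] <- biomeshift::SENTINEL
  m
}

# a zonal layout in which neighbouring bands often share a megabiome, so
# biome- and megabiome-level change genuinely differ
mixed_layout <- c(23L, 24L, 10L, 11L, 7L, 20L, 16L, 1L, 2L)
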