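test_that("overlap proportion: identity, half-shift and new-biome cases", {
  set.seed(14)
  g <- toy_grid(random_codes(4, 8))
  ov <- overlap_proportion(g, g)
  expect_equal(ov$overlap, rep(1, nrow(ov)))

  # biome 1 occupies {c1,c2} before and {c2,c3} after, equal areas -> 0.5
  prev <- toy_grid(matrix(c(1L, 1L, 2L, 2L), 1))
  cur <- toy_grid(matrix(c(2L, 1L, 1L, 2L), 1))
  ov2 <- overlap_proportion(cur, prev)
  expect_equal(ov2$overlap[ov2$code == 1], 0.5)

  # newly appearing biome -> 0
  cur3 <- toy_grid(matrix(c(9L, 1L, 1L, 2L), 1))
  ov3 <- overlap_proportion(cur3, prev)
  expect_equal(ov3$overlap[ov3$code == 9], 0)
})

test_that("non-adjacent fraction: unchanged grids, isolated cells, diagonal contact", {
  set.seed(15)
  g <- toy_grid(random_codes(4, 8))
  na0 <- non_adjacent_fraction(g, g)
  expect_equal(na0$non_adjacent, rep(0, nrow(na0)))

  # biome 9 appears in a cell whose whole neighbourhood lacked it before:
  # its only cell is non-adjacent -> fraction 1
  prev <- toy_grid(matrix(2L, 5, 5))
  cur_m <- matrix(2L, 5, 5); cur_m[3, 3] <- 9L
  cur <- toy_grid(cur_m)
  na1 <- non_adjacent_fraction(cur, prev, wrap = FALSE)
  expect_equal(na1$non_adjacent[na1$code == 9], 1)

  # diagonal-only contact counts under 8- but not 4-connectivity
  prev_m <- matrix(2L, 5, 5); prev_m[2, 2] <- 9L
  prev2 <- toy_grid(prev_m)
  na8 <- non_adjacent_fraction(cur, prev2, connectivity = 8, wrap = FALSE)
  na4 <- non_adjacent_fraction(cur, prev2, connectivity = 4, wrap = FALSE)
  expect_equal(na8$non_adjacent[na8$code == 9], 0)
  expect_equal(na4$non_adjacent[na4$code == 9], 1)

  # a cell that itself held the biome previously is adjacent by convention
  na_self <- non_adjacent_fraction(prev2, prev2, connectivity = 4)
  expect_equal(na_self$non_adjacent, rep(0, 2))
})

test_that("non_adjacent <= 1 - overlap for every biome on random fixtures", {
  set.seed(16)
  for (rep in 1:10) {
    prev <- toy_grid(random_codes(10, 20, codes = 1:4))
    cur <- toy_grid(random_codes(10, 20, codes = 1:4))
    for (conn in c(4, 8)) for (wrap in c(TRUE, FALSE)) {
      ov <- overlap_proportion(cur, prev)
      na_ <- non_adjacent_fraction(cur, prev, connectivity = conn, wrap = wrap)
      expect_identical(na_$code, ov$code)
      expect_true(all(na_$non_adjacent <= 1 - ov$overlap + 1e-12))
    }
  }
})

test_that("label_patches matches stated examples", {
  expect_identical(unname(label_patches(toy_grid(matrix(3L, 4, 6)))$counts), 1L)

  # two blocks of biome 1 separated by biome 2
  m <- matrix(2L, 3, 7)
  m[, 1:2] <- 1L; m[, 6:7] <- 1L
  pl <- label_patches(toy_grid(m), wrap = FALSE)
  expect_identical(unname(pl$counts[c("1", "2")]), c(2L, 1L))

  # the same block spans the antimeridian: 1 patch with wrap, 2 without
  expect_identical(unname(label_patches(toy_grid(m), wrap = TRUE)$counts["1"]),
                   1L)

  # patches partition the biome's cells
  expect_identical(sort(unique(pl$labels[m == 1])), c(1L, 3L))
  expect_true(all(pl$labels[m != biomeshift::SENTINEL] > 0))
})

test_that("label_patches agrees with the recursive flood-fill oracle", {
  # trimmed-down version of the acceptance sweep (full 200-grid run there)
  set.seed(17)
  for (rep in 1:25) {
    m <- random_codes(12, 12, codes = 1:3, p_sentinel = 0.3)
    g <- toy_grid(m)
    for (conn in c(4, 8)) for (wrap in c(TRUE, FALSE)) {
      got <- label_patches(g, connectivity = conn, wrap = wrap)$counts
      want <- oracle_patch_counts(m, conn, wrap)
      expect_identical(got[order(as.integer(names(got)))], want)
    }
  }
})

test_that("biome_centroid handles single cells, symmetric pairs and parallels", {
  g1 <- biome_grid(matrix(1L, 1, 1), grid_geometry(1, 1, 1, 1,
                                                   origin = c(10, 20)))
  expect_equal(unname(biome_centroid(g1, 1)), c(10, 20), tolerance = 1e-9)

  # two equal-area cells at (0, +-10) -> (0, 0)
  g2 <- biome_grid(matrix(c(1L, SENTINEL, 1L), 1),
                   grid_geometry(1, 3, 1, 10, origin = c(0, -10)))
  expect_equal(unname(biome_centroid(g2, 1)), c(0, 0), tolerance = 1e-9)

  # three equal-area cells on one parallel vs a direct 3-D vector sum
  lat <- 40
  g3 <- biome_grid(matrix(1L, 1, 3), grid_geometry(1, 3, 1, 25,
                                                   origin = c(lat, 0)))
  d2r <- pi / 180
  v <- colSums(cbind(cos(lat * d2r) * cos(c(0, 25, 50) * d2r),
                     cos(lat * d2r) * sin(c(0, 25, 50) * d2r),
                     rep(sin(lat * d2r), 3)))
  v <- v / sqrt(sum(v^2))
  expect_equal(unname(biome_centroid(g3, 1)),
               c(asin(v[3]) / d2r, atan2(v[2], v[1]) / d2r),
               tolerance = 1e-9)

  expect_error(biome_centroid(g3, 5), "absent")

  # antipodally balanced pair has no defined centroid
  g4 <- biome_grid(matrix(1L, 1, 2), grid_geometry(1, 2, 1, 180,
                                                   origin = c(0, -90)))
  expect_error(biome_centroid(g4, 1), "degenerate centroid")
})

test_that("centroid agrees with an independent per-cell summation", {
  set.seed(18)
  g <- toy_grid(random_codes(8, 16, codes = 1L, p_sentinel = 0.4), step = 3)
  areas <- build_area_vector(g$geometry)
  d2r <- pi / 180
  lats <- row_lats(g$geometry); lons <- col_lons(g$geometry)
  acc <- c(0, 0, 0); wtot <- 0
  for (r in 1:8) for (c in 1:16) if (g$codes[r, c] == 1L) {
    w <- areas[r]
    acc <- acc + w * c(cos(lats[r] * d2r) * cos(lons[c] * d2r),
                       cos(lats[r] * d2r) * sin(lons[c] * d2r),
                       sin(lats[r] * d2r))
    wtot <- wtot + w
  }
  v <- acc / wtot; v <- v / sqrt(sum(v^2))
  expect_equal(unname(biome_centroid(g, 1)),
               c(asin(v[3]) / d2r, atan2(v[2], v[1]) / d2r),
               tolerance = 1e-9)
})

test_that("centroid_step reproduces haversine distances and compass bearings", {
  s <- centroid_step(c(0, 0), c(0, 10))
  expect_equal(unname(s["bearing_deg"]), 90)
  expect_equal(unname(s["distance_km"]),
               oracle_haversine(c(0, 0), c(0, 10)), tolerance = 1e-12)
  expect_equal(unname(centroid_step(c(0, 0), c(0, 1))["distance_km"]),
               111.19, tolerance = 1e-4)
  expect_equal(unname(centroid_step(c(0, 0), c(10, 0))["bearing_deg"]), 0)
  expect_equal(unname(centroid_step(c(0, 0), c(-10, 0))["bearing_deg"]), 180)
  expect_equal(unname(centroid_step(c(45, 170), c(45, -170))["bearing_deg"]),
               centroid_step(c(45, 0), c(45, 20))[["bearing_deg"]])
  expect_identical(unname(centroid_step(c(12, 34), c(12, 34))),
                   c(0, 0))
})

test_that("pure northward drift yields near-meridional centroid tracks", {
  # one-hemisphere scenario, drift of exactly one row per slice, no noise;
  # land restricted to a continental-scale 30-degree sector so zonal bands
  # have a defined centroid longitude (a full ring's 3-D mean sits on the
  # rotation axis)
  geom <- grid_geometry(50, 72, 1, 5, origin = c(54.5, -177.5))
  sp <- scenario_spec(geom, n_slices = 4, zonal_layout = c(24L, 10L, 7L, 20L, 21L),
                      per_slice_change_rate = 0, drift_deg_per_slice = 1,
                      boundary_jitter_deg = 0, ocean_fraction = 0, seed = 1)
  gr <- make_scenario(sp)
  sector <- abs(col_lons(geom)) <= 15
  gr <- lapply(gr, function(g) {
    g$codes[, !sector] <- SENTINEL
    biome_grid(g$codes, geom, slice_label = g$slice_label)
  })
  tr <- centroid_track(gr)
  # interior bands only (edge bands gain/lose rows at the grid boundary)
  steps <- tr[tr$code %in% c(10L, 7L, 20L) & !is.na(tr$step_km), ]
  expect_true(nrow(steps) >= 6)
  expect_true(all(pmin(steps$bearing_deg, 360 - steps$bearing_deg) < 5))
  expect_true(all(abs(steps$step_km - 111.19) / 111.19 < 0.1))
})

test_that("centroid_track records gaps for absent biomes", {
  a <- toy_grid(matrix(c(1L, 2L), 1, 2))
  b <- toy_grid(matrix(c(1L, 1L), 1, 2))
  b$slice_label <- "2020-2040"
  tr <- centroid_track(list(a, b))
  expect_true(is.na(tr$lat[tr$code == 2 & tr$slice_label == "2020-2040"]))
  expect_false(anyNA(tr$lat[tr$code == 1]))
})
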