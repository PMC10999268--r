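test_that("cell_area matches the spherical-zone values and the quadrature oracle", {
  # standard 0.5 degree equatorial cell: ~3091 km^2 (quoted as approx. 3100)
  expect_equal(cell_area(-0.25, 0.25, 0.5, 6371), 3091.068, tolerance = 1e-6)

  # full 0.5 degree grid covers the sphere
  g <- global_geometry(0.5)
  expect_equal(sum(build_area_vector(g)) * g$n_lon, 4 * pi * 6371^2,
               tolerance = 1e-6)

  # agreement with midpoint quadrature on a fixed cell and 100 random cells
  expect_equal(cell_area(59.75, 60.25, 0.5),
               oracle_cell_area(59.75, 60.25, 0.5), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:100) {
    s <- runif(1, -90, 85)
    n <- min(s + runif(1, 0.01, 5), 90)
    w <- runif(1, 0.01, 10)
    expect_equal(cell_area(s, n, w), oracle_cell_area(s, n, w),
                 tolerance = 1e-9)
  }
})

test_that("cell_area validates geometry and decreases poleward", {
  expect_error(cell_area(10, 5, 0.5), "invalid geometry")
  expect_error(cell_area(-95, -85, 0.5), "invalid geometry")
  expect_error(cell_area(0, 1, -0.5), "invalid geometry")
  bands <- cell_area(seq(0, 89, 1), seq(1, 90, 1), 1)
  expect_true(all(diff(bands) < 0))
  expect_true(all(bands > 0))
})

test_that("build_area_vector is palindromic on equator-symmetric grids and matches cell_area", {
  g <- global_geometry(2)
  a <- build_area_vector(g)
  expect_equal(a, rev(a))
  lats <- row_lats(g)
  expect_equal(a, cell_area(lats - 1, lats + 1, 2, g$radius_km))
})

test_that("the packaged scheme has 26 biomes in 9 megabiomes, total and single-valued", {
  s <- biome_scheme()
  expect_identical(nrow(s), 26L)
  expect_identical(sort(s$code), 1:26)
  expect_identical(length(unique(s$megabiome)), 9L)
  expect_false(anyNA(s$megabiome))
  # each biome belongs to exactly one megabiome by construction (one row each)
  expect_identical(anyDuplicated(s$code), 0L)
})

test_that("megabiome aggregation follows the published mapping", {
  s <- biome_scheme()
  abbr <- stats::setNames(s$code, s$abbreviation)
  grid <- toy_grid(matrix(c(abbr[["TrEB"]], abbr[["De"]], abbr[["CdEN"]],
                            SENTINEL), 1))
  mg <- aggregate_megabiomes(grid, s)
  mb <- megabiomes(s)
  got <- mb$name[match(mg$codes[1, 1:3], mb$code)]
  expect_identical(got, c("tropical forest", "desert", "boreal forest"))
  expect_identical(mg$codes[1, 4], SENTINEL)
  expect_identical(mg$level, "megabiome")
})

test_that("aggregation is surjective onto 9 classes and flags unknown codes", {
  grid <- toy_grid(matrix(1:26, 2, 13))
  mg <- aggregate_megabiomes(grid)
  expect_identical(sort(unique(as.vector(mg$codes))), 1:9)
  bad <- toy_grid(matrix(c(1L, 99L, 2L, 3L), 2))
  expect_error(aggregate_megabiomes(bad), "unknown biome code 99.*row 2, col 1")
})

test_that("ASCII raster round-trip preserves codes, geometry and sentinels", {
  set.seed(1)
  g <- biome_grid(random_codes(12, 24), grid_geometry(12, 24, 0.5, 0.5,
                                                      origin = c(40, -5.75)))
  p <- withr::local_tempfile(fileext = ".asc")
  write_biome_grid(g, p)
  h <- read_biome_grid(p)
  expect_identical(h$codes, g$codes)
  expect_equal(h$geometry$origin, g$geometry$origin)
  expect_equal(h$geometry$lat_step, g$geometry$lat_step)
})

test_that("rasters with 0-360 longitudes are normalized to -180..180 on read", {
  # two-column grid labelled so values identify their original longitude:
  # centres at 90E and 270E (= -90W); after reading, -90 must come first
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner -90",
               "cellsize 180", "NODATA_value -1", "5 9"), p)
  g <- read_biome_grid(p)
  expect_equal(unname(g$geometry$origin["lon"]), -90)
  expect_identical(as.vector(g$codes), c(9L, 5L))

  # standard global 0.5 degree raster is accepted as-is
  q <- withr::local_tempfile(fileext = ".asc")
  big <- biome_grid(matrix(1L, 360, 720), global_geometry(0.5))
  write_biome_grid(big, q)
  expect_identical(read_biome_grid(q)$geometry$n_lon, 720L)
})

test_that("malformed rasters give format errors", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -1", "1.5 2"), p)
  expect_error(read_biome_grid(p), "non-integer")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -1", "1 2"), p)
  expect_error(read_biome_grid(p), "expected 4 values")
})

test_that("grid and label validation catches bad input", {
  expect_error(grid_geometry(400, 720, 0.5, 0.5), "exceeds 180")
  expect_error(biome_grid(matrix(1L, 2, 2), toy_geom(2, 3)), "dimensions")
  expect_error(biome_grid(matrix(1L, 1, 2), toy_geom(1, 2),
                          slice_label = "1999-2019"), "2000..2480")
  expect_error(biome_grid(matrix(1L, 1, 2), toy_geom(1, 2),
                          slice_label = "2000-2021"), "20-year")
  expect_identical(unname(biomeshift:::parse_slice_label("2480-2500")),
                   c(2480L, 2500L))
})
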