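#' Regular latitude-longitude grid geometry
#'
#' Describes a cell-centre registered regular grid. Row 1 is the northernmost
#' row; column 1 is the westernmost column; longitudes are normalized to
#' `[-180, 180)`. Cell (1,1)'s centre is at `origin`.
#'
#' @param n_lat Integer number of latitude rows.
#' @param n_lon Integer number of longitude columns.
#' @param lat_step Cell height in degrees.
#' @param lon_step Cell width in degrees.
#' @param origin Numeric length-2 `(lat, lon)` of the centre of cell (1,1).
#'   Defaults to the north-west corner cell of a global grid with the given
#'   steps.
#' @param radius_km Earth radius in km (spherical Earth; default 6371.0).
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(360, 720, 0.5, 0.5)   # standard global 0.5 degree grid
#' @export
grid_geometry <- function(n_lat, n_lon, lat_step, lon_step,
                          origin = c(90 - lat_step / 2, -180 + lon_step / 2),
                          radius_km = 6371.0) {
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  stopifnot(n_lat >= 1, n_lon >= 1, lat_step > 0, lon_step > 0,
            length(origin) == 2, radius_km > 0)
  if (n_lat * lat_step > 180 + 1e-9)
    stop("invalid geometry: n_lat * lat_step exceeds 180 degrees")
  north_edge <- origin[1] + lat_step / 2
  south_edge <- origin[1] - (n_lat - 1) * lat_step - lat_step / 2
  if (north_edge > 90 + 1e-9 || south_edge < -90 - 1e-9)
    stop("invalid geometry: grid extends beyond the poles")
  g <- structure(list(
    n_lat = n_lat, n_lon = n_lon,
    lat_step = lat_step, lon_step = lon_step,
    origin = c(lat = unname(origin[1]), lon = unname(normalize_lon(origin[2]))),
    registration = "cell-center",
    radius_km = radius_km
  ), class = "grid_geometry")
  g
}

#' Global grid geometry at a given resolution
#'
#' @param step Cell size in degrees; must divide 180 evenly.
#' @param radius_km Earth radius in km.
#' @return A `grid_geometry` covering the whole sphere.
#' @export
global_geometry <- function(step = 0.5, radius_km = 6371.0) {
  n_lat <- round(180 / step); n_lon <- round(360 / step)
  if (abs(n_lat * step - 180) > 1e-9)
    stop("step must divide 180 degrees evenly")
  grid_geometry(n_lat, n_lon, step, step, radius_km = radius_km)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells, %g x %g deg, origin (%g, %g), R = %g km\n",
              x$n_lat, x$n_lon, x$lat_step, x$lon_step,
              x$origin["lat"], x$origin["lon"], x$radius_km))
  invisible(x)
}

# wrap longitudes into [-180, 180)
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Cell-centre latitudes by row / longitudes by column
#'
#' @param geometry A `grid_geometry`.
#' @return Numeric vector of centre coordinates (row 1 = northernmost,
#'   column 1 = westernmost).
#' @export
row_lats <- function(geometry) {
  geometry$origin["lat"] - (seq_len(geometry$n_lat) - 1) * geometry$lat_step
}

#' @rdname row_lats
#' @export
col_lons <- function(geometry) {
  normalize_lon(geometry$origin["lon"] +
                  (seq_len(geometry$n_lon) - 1) * geometry$lon_step)
}

geometry_equal <- function(a, b, tol = 1e-9) {
  a$n_lat == b$n_lat && a$n_lon == b$n_lon &&
    abs(a$lat_step - b$lat_step) < tol && abs(a$lon_step - b$lon_step) < tol &&
    abs(a$origin["lat"] - b$origin["lat"]) < tol &&
    abs(normalize_lon(a$origin["lon"] - b$origin["lon"])) < tol
}

#' Surface area of a latitude-longitude cell on the sphere
#'
#' Spherical-zone formula `A = R^2 * dlambda * (sin(phi_n) - sin(phi_s))`,
#' with `dlambda` the cell width in radians. Area depends only on the
#' latitude bounds, not on longitude. For the standard 0.5 degree grid this
#' gives ~3091 km^2 at the equator.
#'
#' @param lat_south,lat_north Southern and northern cell edges in degrees;
#'   `-90 <= lat_south < lat_north <= 90`. Vectorized.
#' @param lon_step Cell width in degrees (> 0).
#' @param radius_km Sphere radius in km.
#' @return Cell area(s) in km^2.
#' @examples
#' cell_area(-0.25, 0.25, 0.5)        # ~3091 km^2
#' @export
cell_area <- function(lat_south, lat_north, lon_step, radius_km = 6371.0) {
  if (any(lon_step <= 0)) stop("invalid geometry: lon_step must be positive")
  if (any(lat_south < -90 - 1e-12) || any(lat_north > 90 + 1e-12))
    stop("invalid geometry: latitudes outside [-90, 90]")
  if (any(lat_south >= lat_north))
    stop("invalid geometry: lat_south must be strictly less than lat_north")
  d2r <- pi / 180
  radius_km^2 * (lon_step * d2r) *
    (sin(lat_north * d2r) - sin(lat_south * d2r))
}

#' Per-row cell areas for a grid
#'
#' On a regular longitude grid, area is constant along a row, so one value
#' per latitude row suffices for all area weighting.
#'
#' @param geometry A `grid_geometry`.
#' @return Numeric vector of length `n_lat`; entry i is the area (km^2) of
#'   every cell in row i.
#' @export
build_area_vector <- function(geometry) {
  lats <- row_lats(geometry)
  cell_area(lats - geometry$lat_step / 2, lats + geometry$lat_step / 2,
            geometry$lon_step, geometry$radius_km)
}

#' Latitude band of a cell-centre latitude
#'
#' Assigns low (|lat| < 30), mid (30 <= |lat| < 60) and high (|lat| >= 60)
#' bands by cell centre. A centre at exactly +-30 falls in mid and at +-60 in
#' high (half-open toward the equator).
#'
#' @param lat Numeric vector of latitudes in degrees.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
lat_band <- function(lat) {
  a <- abs(lat)
  factor(ifelse(a < 30, "low", ifelse(a < 60, "mid", "high")),
         levels = c("low", "mid", "high"))
}
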