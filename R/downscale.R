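#' Monthly climate field on a regular grid
#'
#' @param variable One of `"temperature"`, `"precipitation"`,
#'   `"cloud"`.
#' @param data Numeric array `12 x n_lat x n_lon` (months first).
#' @param geometry A `grid_geometry`.
#' @return An object of class `climate_field`.
#' @export
climate_field <- function(variable = c("temperature", "precipitation", "cloud"),
                          data, geometry) {
  variable <- match.arg(variable)
  stopifnot(inherits(geometry, "grid_geometry"), is.array(data))
  if (length(dim(data)) != 3 ||
      !all(dim(data) == c(12, geometry$n_lat, geometry$n_lon)))
    stop("data must be a 12 x n_lat x n_lon array")
  if (variable == "precipitation" && any(data < 0))
    stop("precipitation must be non-negative")
  if (variable == "cloud" && (any(data < 0) || any(data > 1)))
    stop("cloud fraction must lie in [0, 1]")
  structure(list(variable = variable, data = data, geometry = geometry),
            class = "climate_field")
}

# bilinear interpolation of one coarse matrix onto fine cell centres, with
# longitudinal wrap (the coarse grid is globally periodic) and latitude
# clamped beyond the outermost coarse row centres
interp_bilinear <- function(m, coarse, fine) {
  src_lat <- row_lats(coarse); src_lon <- col_lons(coarse)
  dst_lat <- row_lats(fine); dst_lon <- col_lons(fine)
  nr <- length(src_lat)

  # rows: src_lat is decreasing; clamp outside
  i1 <- findInterval(-dst_lat, -src_lat)          # index of row at/above
  i1 <- pmin(pmax(i1, 1L), nr)
  i2 <- pmin(i1 + 1L, nr)
  denom <- src_lat[i1] - src_lat[i2]
  ty <- ifelse(denom == 0, 0, (src_lat[i1] - dst_lat) / denom)
  ty <- pmin(pmax(ty, 0), 1)

  # columns: periodic in longitude
  nc <- length(src_lon)
  step <- coarse$lon_step
  off <- normalize_lon(dst_lon - src_lon[1])
  off[off < 0] <- off[off < 0] + 360
  j1 <- (floor(off / step) %% nc) + 1L
  j2 <- (j1 %% nc) + 1L
  tx <- (off - (j1 - 1L) * step) / step
  tx <- pmin(pmax(tx, 0), 1)

  out <- matrix(0, fine$n_lat, fine$n_lon)
  for (jj in seq_len(fine$n_lon)) {
    a <- m[i1, j1[jj]] * (1 - ty) + m[i2, j1[jj]] * ty
    b <- m[i1, j2[jj]] * (1 - ty) + m[i2, j2[jj]] * ty
    out[, jj] <- a * (1 - tx[jj]) + b * tx[jj]
  }
  out
}

#' Anomaly ("delta") downscaling of a coarse climate field
#'
#' Computes the coarse anomaly of a future period relative to a
#' pre-industrial period, interpolates it bilinearly (with longitudinal
#' wrap) onto the fine reference grid, and applies it to an observed fine
#' reference climatology. Temperature and cloud use additive anomalies
#' (cloud clipped to `[0, 1]`); precipitation defaults to ratio anomalies —
#' the future/pre-industrial ratio, capped at `ratio_cap` and set to 1 where
#' the pre-industrial value is below `ratio_threshold` — so that dry-cell
#' artifacts and negative rainfall cannot arise. Additive precipitation
#' (floored at 0) is available via `mode = "additive"`.
#'
#' @param future_coarse,preindustrial_coarse `climate_field`s on the same
#'   coarse geometry and of the same variable.
#' @param reference_fine A `climate_field` of the same variable on the fine
#'   (output) geometry.
#' @param mode `"auto"` (additive for temperature/cloud, ratio for
#'   precipitation), `"additive"`, or `"ratio"`.
#' @param ratio_cap Maximum precipitation ratio (default 5).
#' @param ratio_threshold Pre-industrial precipitation (mm/month) below
#'   which the ratio is defined as 1 (default 0.1).
#' @return A `climate_field` on the fine geometry.
#' @export
downscale_anomaly <- function(future_coarse, preindustrial_coarse,
                              reference_fine,
                              mode = c("auto", "additive", "ratio"),
                              ratio_cap = 5, ratio_threshold = 0.1) {
  mode <- match.arg(mode)
  for (f in list(future_coarse, preindustrial_coarse, reference_fine))
    stopifnot(inherits(f, "climate_field"))
  if (future_coarse$variable != preindustrial_coarse$variable ||
      future_coarse$variable != reference_fine$variable)
    stop("input error: variables differ between fields")
  if (!geometry_equal(future_coarse$geometry, preindustrial_coarse$geometry))
    stop("input error: coarse fields have different geometries")
  variable <- future_coarse$variable
  if (mode == "auto")
    mode <- if (variable == "precipitation") "ratio" else "additive"
  if (mode == "ratio" && variable != "precipitation")
    stop("input error: ratio anomalies only apply to precipitation")

  coarse <- future_coarse$geometry
  fine <- reference_fine$geometry
  out <- reference_fine$data
  for (mo in 1:12) {
    fut <- future_coarse$data[mo, , ]
    pre <- preindustrial_coarse$data[mo, , ]
    ref <- reference_fine$data[mo, , ]
    if (mode == "additive") {
      delta <- interp_bilinear(fut - pre, coarse, fine)
      val <- ref + delta
      if (variable == "cloud") val <- pmin(pmax(val, 0), 1)
      if (variable == "precipitation") val <- pmax(val, 0)
    } else {
      ratio <- ifelse(pre < ratio_threshold, 1, pmin(fut / pre, ratio_cap))
      val <- ref * pmax(interp_bilinear(ratio, coarse, fine), 0)
    }
    out[mo, , ] <- val
  }
  climate_field(variable, out, fine)
}
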