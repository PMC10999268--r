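#' Read / write biome grids as ESRI ASCII rasters
#'
#' Plain-text single-band rasters (`.asc`): a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of integer codes, northernmost row first. Grids whose longitudes run
#' 0-360 are rotated to -180..180 on read; cells must be square and codes
#' integer. `write_biome_grid`/`read_biome_grid` round-trip codes, geometry
#' and sentinel placement exactly.
#'
#' @param path File path.
#' @param slice_label,level,radius_km Metadata attached on read (the format
#'   itself stores only geometry and codes).
#' @return `read_biome_grid`: a `biome_grid`. `write_biome_grid`: `path`,
#'   invisibly.
#' @export
read_biome_grid <- function(path, slice_label = "2000-2020",
                            level = c("biome", "megabiome"),
                            radius_km = 6371.0) {
  level <- match.arg(level)
  r <- read_ascii_raster(path, radius_km = radius_km)
  biome_grid(r$values, r$geometry, slice_label = slice_label, level = level)
}

#' @rdname read_biome_grid
#' @param grid A `biome_grid`.
#' @export
write_biome_grid <- function(grid, path) {
  stopifnot(inherits(grid, "biome_grid"))
  write_ascii_raster(grid$codes, grid$geometry, path)
}

# shared ASCII-grid reader; returns list(values = integer matrix, geometry)
read_ascii_raster <- function(path, radius_km = 6371.0) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[2]))))
      stop("format error: malformed ASCII raster header in ", path)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("format error: missing header fields in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  vals <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  if (length(vals) != nc * nr)
    stop("format error: expected ", nc * nr, " values, found ", length(vals))
  if (any(vals != round(vals)))
    stop("format error: non-integer codes in ", path)
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == as.integer(hdr$nodata_value)] <- SENTINEL
  geom <- grid_geometry(nr, nc, cs, cs,
                        origin = c(hdr$yllcorner + nr * cs - cs / 2,
                                   hdr$xllcorner + cs / 2),
                        radius_km = radius_km)
  # rotate 0..360 grids so columns run west to east from -180
  lons_raw <- hdr$xllcorner + (seq_len(nc) - 0.5) * cs
  if (any(lons_raw >= 180)) {
    lons <- normalize_lon(lons_raw)
    ord <- order(lons)
    m <- m[, ord, drop = FALSE]
    geom <- grid_geometry(nr, nc, cs, cs,
                          origin = c(geom$origin["lat"], lons[ord][1]),
                          radius_km = radius_km)
  }
  list(values = m, geometry = geom)
}

write_ascii_raster <- function(values, geometry, path, nodata = SENTINEL) {
  if (abs(geometry$lat_step - geometry$lon_step) > 1e-12)
    stop("ASCII rasters require square cells")
  cs <- geometry$lat_step
  hdr <- c(
    sprintf("ncols %d", geometry$n_lon),
    sprintf("nrows %d", geometry$n_lat),
    sprintf("xllcorner %.10g", geometry$origin["lon"] - cs / 2),
    sprintf("yllcorner %.10g",
            geometry$origin["lat"] - geometry$n_lat * cs + cs / 2),
    sprintf("cellsize %.10g", cs),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(values, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write an anthrome mask raster
#'
#' The raster stores integer class ids; a sidecar CSV (`<path>.classes.csv`
#' by default) maps ids to class names such as `urban`, `wild`. Cells with the
#' NODATA value become non-terrestrial (`NA` class).
#'
#' @param path Raster path.
#' @param classes_path Sidecar CSV with columns `id,class`.
#' @return `read_anthromes`: an `anthrome_mask`.
#' @export
read_anthromes <- function(path, classes_path = paste0(path, ".classes.csv")) {
  r <- read_ascii_raster(path)
  lut <- utils::read.csv(classes_path, stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(lut)))
    stop("format error: class sidecar needs columns id,class")
  cls <- matrix(NA_character_, nrow(r$values), ncol(r$values))
  live <- r$values != SENTINEL
  idx <- match(r$values[live], lut$id)
  if (anyNA(idx)) stop("format error: raster contains ids absent from sidecar")
  cls[live] <- lut$class[idx]
  anthrome_mask(cls, r$geometry)
}

#' @rdname read_anthromes
#' @param mask An `anthrome_mask`.
#' @export
write_anthromes <- function(mask, path,
                            classes_path = paste0(path, ".classes.csv")) {
  stopifnot(inherits(mask, "anthrome_mask"))
  classes <- sort(unique(mask$classes[!is.na(mask$classes)]))
  ids <- seq_along(classes)
  vals <- matrix(SENTINEL, nrow(mask$classes), ncol(mask$classes))
  live <- !is.na(mask$classes)
  vals[live] <- ids[match(mask$classes[live], classes)]
  write_ascii_raster(vals, mask$geometry, path)
  utils::write.csv(data.frame(id = ids, class = classes), classes_path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metrics table to CSV
#'
#' Tidy long-format output; rows are written in a deterministic order so that
#' identical runs give byte-identical files.
#'
#' @param table A data.frame of metric records.
#' @param path Output CSV path.
#' @export
write_metrics <- function(table, path) {
  ord <- do.call(order, unname(as.list(table)))
  utils::write.csv(table[ord, , drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
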