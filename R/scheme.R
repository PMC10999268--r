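#' The 26-biome catalogue and its 9-megabiome grouping
#'
#' Loads the biome classification scheme shipped with the package: 26 biomes
#' (integer codes 1-26 with names and abbreviations) each belonging to exactly
#' one of 9 megabiomes. Megabiomes are assigned integer codes 1-9 in order of
#' first appearance in the table.
#'
#' @param path Optional path to a scheme CSV with columns
#'   `code,name,abbreviation,megabiome`; defaults to the packaged table.
#' @return A data.frame of class `biome_scheme` with columns `code`, `name`,
#'   `abbreviation`, `megabiome`, `megabiome_code`.
#' @examples
#' s <- biome_scheme()
#' table(s$megabiome)
#' @export
biome_scheme <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biome_scheme.csv", package = "biomeshift",
                        mustWork = TRUE)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "abbreviation", "megabiome")
  if (!all(need %in% names(s)))
    stop("scheme CSV must have columns ", paste(need, collapse = ", "))
  s$code <- as.integer(s$code)
  if (anyDuplicated(s$code)) stop("duplicate biome codes in scheme")
  if (anyDuplicated(s$abbreviation)) stop("duplicate abbreviations in scheme")
  mb <- unique(s$megabiome)
  s$megabiome_code <- match(s$megabiome, mb)
  class(s) <- c("biome_scheme", "data.frame")
  s
}

#' Megabiome lookup table of a scheme
#'
#' @param scheme A `biome_scheme`.
#' @return A data.frame with one row per megabiome: `code`, `name`.
#' @export
megabiomes <- function(scheme) {
  u <- !duplicated(scheme$megabiome_code)
  data.frame(code = scheme$megabiome_code[u], name = scheme$megabiome[u])
}

# name lookup used by reporting; works at either classification level
code_names <- function(scheme, level) {
  if (level == "biome") {
    stats::setNames(scheme$name, scheme$code)
  } else {
    mb <- megabiomes(scheme)
    stats::setNames(mb$name, mb$code)
  }
}

#' Aggregate a biome grid to the megabiome level
#'
#' Replaces each biome code by the code of the megabiome it belongs to;
#' sentinel (non-terrestrial) cells are untouched. Aggregation is total:
#' a code not present in the scheme is an error identifying the offending
#' cell.
#'
#' @param grid A `biome_grid` with `level = "biome"`.
#' @param scheme A `biome_scheme` (default: packaged).
#' @return A `biome_grid` with `level = "megabiome"`.
#' @export
aggregate_megabiomes <- function(grid, scheme = biome_scheme()) {
  stopifnot(inherits(grid, "biome_grid"))
  if (grid$level != "biome")
    stop("aggregate_megabiomes expects a biome-level grid")
  codes <- grid$codes
  live <- codes != SENTINEL
  idx <- match(codes[live], scheme$code)
  if (anyNA(idx)) {
    bad <- which(live)[which(is.na(idx))[1]]
    rc <- arrayInd(bad, dim(codes))
    stop(sprintf("unknown biome code %d at cell (row %d, col %d)",
                 codes[bad], rc[1], rc[2]))
  }
  out <- codes
  out[live] <- scheme$megabiome_code[idx]
  biome_grid(out, grid$geometry, slice_label = grid$slice_label,
             level = "megabiome")
}
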