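Package: biomeshift
Title: Quantifying Long-Term Shifts in Climatically Suitable Biome Area
Version: 0.1.0
Authors@R:
    person("biomeshift", "developers", email = "biomeshift@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying change in categorical biome maps on regular
    latitude-longitude grids over multi-century time series. Given one biome
    raster per 20-year time slice (for example, equilibrium vegetation-model
    output under a greenhouse-gas scenario), the package computes area-weighted
    change fractions against the previous slice and against a present-day
    baseline (globally and within low/mid/high latitude bands), total
    climatically suitable area per biome, overlap and non-adjacency proportions
    that proxy required colonization and long-distance migration, great-circle
    centroid tracks with step distance and bearing, and counts of spatially
    segregated patches. Includes the 26-biome to 9-megabiome aggregation
    scheme, two-tier human-land-use (anthrome) masking with grid
    disaggregation, anomaly ("delta") downscaling of monthly climate fields,
    and a seeded synthetic-scenario generator so every stage is testable
    without external model output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
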