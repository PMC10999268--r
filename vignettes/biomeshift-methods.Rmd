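---
title: "Methods: quantifying biome change, migration feasibility and fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying biome change, migration feasibility and fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomeshift)
```

## The model of the data

`biomeshift` operates on *time series of categorical rasters*: one integer
matrix per 20-year slice on a cell-centre registered, regular
latitude–longitude grid (row 1 northernmost, longitudes normalized to
[−180, 180)). The canonical use case is equilibrium vegetation-model output —
a map of which of 26 biomes each cell's climate would support — but nothing
in the metrics assumes a particular upstream model. Two classification levels
are supported: the 26 biomes and a 9-class megabiome grouping
(`biome_scheme()` ships the full mapping; aggregation is total, so an unknown
code is an error naming the offending cell, never a silent drop).

Non-terrestrial cells (ocean, ice, barren, or masked out) carry the sentinel
code −1 and are excluded from every numerator *and* denominator. Because the
upstream land mask is fixed, cells can only change terrestrial status through
masking configuration; comparisons therefore restrict to cells terrestrial in
*both* slices so that fractions are proportions of a well-defined area.

## Area weighting

Every statistic is weighted by spherical cell area,

$$A = R^2\,\Delta\lambda\,(\sin\varphi_n - \sin\varphi_s),$$

with $R$ = 6371 km by default (configurable; the choice of Earth radius
affects absolute km² values by < 0.1% and no fraction at all). The formula is
exact on the sphere, so the full 0.5° grid closes to $4\pi R^2$ to machine
precision, and the areas of a disaggregated cell's children sum exactly to
the parent's area (the sine terms telescope) — which is why masking at child
resolution conserves per-biome area to 10⁻⁹ relative.

## The five statistic families

1. **Change fraction** (`change_fraction`): area-weighted fraction of cells
   whose class differs between a slice and a reference — the previous slice
   (rate of change) or the first slice (cumulative change; the baseline is
   always the series' first slice, labelled 2000–2020). Reported globally and
   within low/mid/high latitude bands (|φ| < 30°, 30–60°, 60–90°, assigned by
   cell centre). A centre at exactly ±30° falls in mid and ±60° in high: the
   boundary is half-open toward the equator, a deterministic documented
   choice where the convention is otherwise unstated. Band fractions are
   normalized by *band* area; numerator and denominator are both written out
   so a global normalization is recoverable.
2. **Suitable area** (`area_by_biome`): km² per code per slice.
3. **Overlap and non-adjacency** (`overlap_proportion`,
   `non_adjacent_fraction`): per biome present at *t*, the share of its area
   lying in cells that carried the same biome in the reference slice; and the
   share lying in cells that neither carried it nor touch any cell that did,
   under 4- or 8-neighbour connectivity with optional antimeridian wrap. A
   cell that itself carried the biome previously counts as adjacent (it
   cannot require long-distance migration). Non-adjacent cells are a subset
   of non-overlapping cells, so `non_adjacent ≤ 1 − overlap` always — this is
   enforced as a property test.
4. **Centroid tracks** (`biome_centroid`, `centroid_step`,
   `centroid_track`): the area-weighted mean of cell-centre *unit vectors in
   3-D*, renormalized to the sphere. Naive lat/lon averaging breaks at the
   antimeridian and at high latitudes; the vector mean does not, at the cost
   of a known degeneracy: an antipodally balanced distribution (e.g. a full
   zonal ring, whose mean vector lies on the rotation axis) has no meaningful
   centroid and is reported as an error when the mean vector norm falls
   below 10⁻⁹. Steps use the haversine distance and initial great-circle
   bearing (0° = north, clockwise); coincident points report bearing 0 by
   convention, and steps under 1 km are flagged `low_confidence` because
   bearing is numerically unstable for tiny displacements.
5. **Patch counts** (`label_patches`): connected components of same-code
   cells. The production path builds a same-code adjacency edge list and uses
   `igraph::components`; the test suite checks it cell-for-cell against an
   independent recursive flood fill on hundreds of random grids. Default
   connectivity is 8 with longitudinal wrap on — the common default of
   landscape-metrics patch routines — but both are flags, recorded in the run
   manifest rather than presented as "the" original setting, because the
   choice is not derivable from the published description.

## Anthrome masking

Human land use is applied as a *static* categorical mask (the upstream
dataset provides no future projections; treating the present-day footprint as
fixed through 2500 is a stated simplification, not a modelling claim). The
biome grid is first disaggregated by an integer factor (0.5° → 1/12° is
factor 6, 36 children per parent) so removal happens cell-for-cell at the
mask's resolution; masks misaligned by more than half a child cell are an
error, never silently resampled. Tier `urban` removes only
`urban`/`dense settlement`; tier `non_wild` keeps only
`wild`/`semi-natural`; tier `none` returns the grid unchanged, keeping the
biome model's own coastline (the masked tiers intersect the two land masks,
which slightly reduces terrestrial area — the same coastline-resolution
effect seen when comparing datasets of different resolutions). Classes
outside the recognized vocabulary are kept at tier `urban` and removed at
`non_wild` (conservative both ways) and counted in a message. Consequences
enforced as properties: per-biome area is monotone none ≥ urban ≥ non_wild;
masking is idempotent; masking commutes with megabiome aggregation.

## The synthetic-scenario generator

`make_scenario` emulates the statistical structure the metrics consume — not
any vegetation physiology:

* **Zonation**: latitude bands carry biomes in a fixed order (default: an
  equator-symmetric tundra / boreal / cool-forest / grassland / desert /
  tropical sequence), with band boundaries perturbed by spatially correlated
  noise (white noise smoothed by a moving-average kernel of length
  `patchiness`, default 2 cells, scaled to `boundary_jitter_deg`, default
  1.5°) so zone edges are patchy like real ecotones.
* **Change**: each slice applies independent per-cell switches with
  probability `per_slice_change_rate` (default 0.12 — the near-term fraction
  of land forced toward a different biome per 20 years that the metrics are
  designed to detect). A switching cell takes the biome of a neighbouring
  latitude band, guaranteed different from its current code, so synthetic
  change resembles climatic forcing at zone edges rather than salt-and-pepper
  noise, and the requested rate is exactly the expected realized rate.
* **Drift**: zone boundaries translate north by `drift_deg_per_slice`
  (signed; poleward tests use hemisphere-limited grids). With noise and
  switching off, drift is the only signal, which is how the centroid tracker
  is validated.
* **Ocean**: a thresholded correlated field marks `ocean_fraction` of cells
  sentinel (default 0.3, continental-scale land masses); the mask is static
  across slices, matching the fixed land mask of equilibrium vegetation
  models.
* **Determinism**: all randomness flows through R's default generator from a
  single integer seed; identical seeds give bit-identical series on any
  platform.

What a green test on synthetic data does *not* establish: realism of biome
geography (bands are idealized), transient vegetation dynamics, dispersal
limitation, or any particular climate sensitivity. The generator validates
the *measurement* machinery; conclusions about the real world require real
model output, which the same pipeline ingests from rasters.

`make_anthromes` quantile-slices one correlated Gaussian field into the
requested class fractions, producing clustered land-use patches with
near-exact realized fractions. Its default mix (1% urban, 2% dense
settlement, 13% cropland, 30% rangeland, 54% wild/semi-natural) is a rough
present-day global composition, chosen once as a realistic testing world.

## Numerical and design choices

* **Raster format**: plain-text ESRI ASCII grids (plus a CSV class sidecar
  for anthromes). The deployment environment provides no netCDF/GeoTIFF R
  bindings, and the text format keeps fixtures human-readable; 0–360°
  rasters are rotated to −180..180° on read, and write→read round-trips are
  exact.
* **Downscaling** (`downscale_anomaly`): coarse future-minus-preindustrial
  anomalies are bilinearly interpolated (longitudes periodic, latitudes
  clamped beyond the outermost coarse centres) and applied additively
  (temperature; cloud, clipped to [0, 1]) or as ratios (precipitation,
  capped at 5 and defined as 1 where the pre-industrial value is below
  0.1 mm/month, so near-zero denominators and negative rainfall cannot
  occur; additive mode with a zero floor is available by flag). The
  interpolation scheme and the precipitation convention are configuration,
  since "standard anomaly method" admits several readings.
* **Tie-breaks and degenerates**: empty (all-sentinel) grids yield empty
  tables, not errors; a biome absent from a slice leaves a gap (NA row) in
  its centroid track rather than a zero; scopes with no terrestrial area
  report NA fractions with zero denominators.
* **Determinism of outputs**: `run_pipeline` writes rows in sorted order and
  a manifest without timestamps, so identical configurations produce
  byte-identical files; the manifest records the config hash, package
  version, connectivity/wrap flags, sentinel value, centroid estimator and
  band-boundary convention.

## Known limitations

* The mask is static in time; land-use change over five centuries will in
  reality interact with biome migration.
* Patch counting and adjacency operate on the grid graph; an 8-neighbour
  step at 60° latitude spans a much shorter east–west distance than at the
  equator, so "adjacency" is a grid notion, not a fixed-kilometre one.
* Centroids of multimodal distributions (e.g. a biome split between
  hemispheres) are well-defined but can sit far from either mode and move
  discontinuously when the balance shifts; interpret tracks together with
  the patch and latitude-band tables.
* No dispersal-rate modelling: non-adjacency flags where long-distance
  migration would be *required*, not whether it is possible.
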