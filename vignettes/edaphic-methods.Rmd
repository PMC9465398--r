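---
title: "Edaphic suitability modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edaphic suitability modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edaphic)
```

## The model

Pine barren, sandplain, heathland and related open-canopy ecosystems are
edaphic specialists: they persist only on deep, excessively drained sandy
soils, and are maintained there by disturbance. That makes two soil
variables — percent sand and depth to the nearest restrictive layer (such as
bedrock) — natural predictors of where such ecosystems *can* occur, in a way
that regional climate variables are not. The model this package implements
is a threshold classification calibrated from the soils under known
high-quality ecosystem remnants.

Soil surveys deliver their information in a nested hierarchy: mapped
polygons (*map units*), each composed of one or more *soil types*
(components) with stated areal fractions, each described by depth-ordered
*horizons*. The model aggregates upward through that hierarchy:

1. **Soil type.** The mean percent sand of a soil type is the mean over its
   entire described profile, weighting each horizon's sand content by the
   horizon's length in cm:
   $$\overline{S}_{\text{type}} = \frac{\sum_{g=1}^{m} L_g\, S_g}{\sum_{g=1}^{m} L_g},$$
   where $L_g$ and $S_g$ are the length and percent sand of horizon $g$ and
   $m$ is the number of horizons. The soil type's depth is the depth to the
   nearest restrictive layer, capped at the maximum reported depth
   (200 cm); a profile with no reported restrictive layer is taken to be
   200 cm deep.
2. **Location.** Each known ecosystem location is intersected with the
   survey polygons; its mean sand and mean depth are the means over its
   constituent soil types weighted by each type's area within the location
   (polygon-intersection area times the component's areal fraction).
3. **Calibration.** Locations are split at random into a training set
   (default 70%, size rounded half-up, so 156 locations give 109 training
   and 47 validation) and a held-out set. Over the training locations the
   model computes the area-weighted mean and area-weighted SD of location
   mean sand and depth, weighting each location by its area, and sets the
   suitability thresholds one SD below each mean.
4. **Classification.** Every map unit whose fraction-weighted mean sand
   *and* depth are at least the thresholds (inclusive comparison — "at
   least as sandy and deep") is suitable; wetland and open-water cells are
   excluded regardless of soil; map units without sand data are `nodata`,
   never `unsuitable`.

Validation asks how much of what the model should capture it does capture:
the overlap of the held-out locations with the suitable map, the overlap of
non-focal ecosystem types (which the map should largely avoid), and the
fraction of species occurrence points whose cell is suitable.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cap_depth` | 200 | cm | maximum depth soil surveys describe; deeper or unreported restrictive layers are treated as 200 cm |
| `fraction` | 0.7 | — | training share of locations; 0.7 of 156 rounds (half-up) to 109 |
| `rounding` | `"integer"` | — | thresholds are applied as integers; rounding happens after the mean − SD subtraction, on full-precision values |
| `cellsize` | 10 | m | suitability raster resolution, matching gridded soil surveys |
| `coverage_cutoff` | 0.5 | — | binarisation cutoff for "a held-out location fell within the map" |

Three aggregation conventions are deliberate and worth knowing:

* **Horizons with missing sand are excluded with weight renormalisation**,
  never imputed and never treated as 0% sand (0 is a legal sand content).
  A soil type or location whose entire composition lacks sand data is
  flagged and excluded from calibration, and counted in the fit object.
* **Horizon weighting is not truncated at `cap_depth`.** The profile mean
  covers the entire described profile; the cap applies only to the
  restrictive-layer depth. This follows the aggregation rule's wording
  ("entire soil profile") and is not configurable.
* **The weighted SD is the population form** (divide by the summed
  weights). It is the simplest well-defined estimator, reduces to the
  ordinary population SD under equal weights, and equals the unweighted
  population SD of the values replicated in proportion to their weights —
  which is how the unit tests check it.

Two orderings were genuinely open. Whether the published thresholds were
derived from rounded or unrounded means cannot be recovered from the
printed values; this package subtracts unrounded mean and SD, then rounds
half-up, and keeps the raw thresholds in the fit object. And whether a
polygon location "fell within" the map (any overlap? majority? centroid?)
is undefined in common usage; the validation report therefore emits both
the continuous per-location overlap fraction and a binarised summary at a
configurable cutoff rather than guessing a single rule.

## Geometry and rasters

The package computes planar geometry itself: shoelace areas,
Sutherland–Hodgman clipping for polygon intersection, and even–odd
point-in-polygon tests, all in projected metre coordinates. Clipping
against a convex window is exact, so **map-unit polygons must be convex
rings** (grid and Voronoi tessellations are); location, region and
occurrence polygons may be arbitrary simple rings without holes. Geodesic
area is out of scope — inputs are assumed to be in a projected CRS, and a
GeoJSON file without a declared CRS is assumed planar metres with a
warning. Rasters are single-band regular grids, read and written as ESRI
ASCII grids; a coarser exclusion or land-cover raster is co-registered to
the soil grid by nearest-neighbour resampling. Polygon overlap with the
suitability map is evaluated on the raster (cells whose centre falls in the
polygon), with sub-cell polygons falling back to the cell under their
centroid; point–cell membership uses half-open intervals so no point
belongs to two cells, and points off the map count as non-overlapping.

Sliver intersections below 1 m² are discarded as overlay noise. Ties at
the threshold boundary are suitable by the inclusive rule. Degenerate
inputs error early with the offending map unit, soil type or location named
in the message.

## What the synthetic generator emulates

Real inputs at landscape scale — a gridded soil survey, a 30 m land-cover
product, heritage-program ecosystem locations and species records — are not
redistributable at package scale, so `generate_scenario()` builds a
landscape with the same statistical structure and full ground-truth
bookkeeping:

* a square landscape (default 50 km × 50 km) tessellated into 1 km² map
  units, with contiguous **sandy patches** (default 12% of units, grown
  from 5 seeds) in a loamier, shallower background;
* component percent sand drawn from a truncated normal — patch
  Normal(87, 11), background Normal(45, 15), truncated to [0, 100] — and
  restrictive depth from patch Normal(193, 33) and background
  Normal(90, 40), with draws at or beyond 200 cm written as "no restrictive
  layer reported". These patch parameters mirror the training statistics a
  calibration of this kind typically prints, so the default scenario
  calibrates to thresholds near 76% sand and 160 cm depth;
* 1–3 components per unit with Dirichlet areal fractions, 2–5 horizons per
  component with uniform-cut boundaries and ±4 percentage-point
  horizon-level sand scatter, and 2% of horizons with unreported sand;
* 156 ecosystem locations (rotated rectangles, log-uniform 5–30 ha,
  realistic for remnant patches) placed on patch units with bias 1 by
  default — known high-quality remnants sit on suitable soil by
  construction; the bias is a config field exercised by tests;
* a 30 m land-cover raster with NLCD-style codes whose class mix is
  conditioned on patch membership (patch cells lean forest/urban, the
  background leans forest/agriculture), including water and wetland cells
  so the exclusion mask is exercised;
* species occurrence groups whose points land on truly suitable units with
  the group's affinity probability (defaults 0.87 for high-affinity groups,
  0.6 otherwise) and uniformly elsewhere.

Every ground-truth quantity — per-unit and per-location true means, the
true thresholds implied by the generated locations, the true suitable area,
realised land-cover counts — is computed from the same random draws that
produced the data, never re-estimated, and written into the scenario
manifest. Locations are placed wholly inside one map unit so their truth is
exactly that unit's truth; multi-unit composition is exercised separately
by unit tests with hand-built geometries.

What passing tests on this generator do **not** show: real soil surveys
have non-convex, irregularly sized map units, spatially autocorrelated
properties beyond the patch structure, correlated sand and depth, and
systematic survey error; none of these are modelled, so performance on the
synthetic landscape bounds correctness of the arithmetic and overlay, not
accuracy on real terrain.

## Problem sizes used by the test suite

Unit tests run on two-unit hand-built surveys and 10 km × 10 km scenarios.
The recovery test runs 20 seeds of the full-size scenario (50 km × 50 km,
2500 map units, 200 locations) and checks that the calibrated area-weighted
means sit within two standard errors of the generator's truth and that the
end-to-end suitable area matches the truth table within 2%; suitability
rasters there use 50 m cells, which is exact for the grid-aligned map units
while keeping the loop under a minute. The full pipeline with a 10 m
suitability raster and a 30 m land-cover raster runs in well under a minute
on one core.

## Known limitations

* No general polygon–polygon boolean overlay: map units must be convex.
* No reprojection — all layers must already share a planar metre CRS.
* No texture-class inference: percent sand must be numeric input.
* Single land-cover snapshot; no change analysis.
* One random split; repeated-split uncertainty is left to the user (loop
  over seeds of `edaphic_fit()`).
* Overlapping ecosystem locations are treated independently.
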