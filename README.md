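# edaphic

Habitat suitability modelling for ecosystems controlled by soil, not
climate. Pine barrens, sandplains, heathlands and related open-canopy
ecosystems occur only on deep, excessively drained sandy soils; `edaphic`
finds everywhere on a landscape whose soils are at least as sandy and deep
as the soils under known high-quality remnants, for conservation planners
deciding where such ecosystems could be protected or restored.

## The model

Soil surveys describe a landscape as map-unit polygons, each a mix of soil
types (components) with areal fractions, each soil type a stack of
horizons. The package aggregates upward and calibrates a threshold rule:

* **soil type**: depth-weighted mean percent sand over the profile,
  $\overline{S} = \sum_g L_g S_g / \sum_g L_g$ (horizon lengths $L_g$ in
  cm), and depth to the nearest restrictive layer, capped at 200 cm;
* **location**: area-weighted means over the soil types intersecting each
  known ecosystem location;
* **thresholds**: locations are split 70/30 into training and validation
  sets; over the training set the area-weighted mean and SD of location
  mean sand and depth are computed (locations weighted by area), and the
  suitability thresholds are set one SD below each mean — a soil is
  suitable when sand *and* depth are at least the thresholds (inclusive);
* **map**: every map unit is classified, wetland/open-water cells are
  excluded, and the map is validated by its overlap with held-out
  locations, non-focal ecosystems, and species occurrence points.

A seeded synthetic-landscape generator with full ground-truth bookkeeping
(`generate_scenario()`) stands in for the non-redistributable survey,
land-cover and heritage-program inputs, so every stage is testable offline.

## Worked example

```r
library(edaphic)

scenario <- generate_scenario(synthetic_config(seed = 42))   # 50 x 50 km landscape
comp     <- compose_locations(scenario$locations, scenario$survey)
fit      <- edaphic_fit(comp, fraction = 0.7, seed = 42)
fit
#> Edaphic suitability model
#>   training locations: 109 (validation held out: 47)
#>   area-weighted sand:  85.7 % (SD 7.9)
#>   area-weighted depth: 183.3 cm (SD 18.6)
#>   thresholds (mean - 1 SD): >= 78 % sand and >= 165 cm depth
```

109 of the 156 generated locations train the model; the calibrated
thresholds say a soil qualifies when its profile is at least 78% sand and
at least 165 cm deep (one area-weighted SD below the training means).
Classify the landscape and see what currently grows on the suitable soils:

```r
map <- suitability_map(scenario$survey, fit,
                       exclusion = exclusion_mask(scenario$landcover),
                       cellsize = 10)
map
#> <suitability_map> 2500 map unit(s), 10 m cells, CRS local-metre
#>   rule: sand >= 78 %, depth >= 165 cm
#>   suitable 197.8 km^2, unsuitable 2117.1 km^2, excluded 185.0 km^2

summarize_cover(map, scenario$landcover)[, c("category", "area_km2", "prop_of_suitable")]
#>      category area_km2 prop_of_suitable
#> 1      forest 112.4080       0.56823059
#> 2        open   8.1572       0.04123524
#> 3 agriculture  24.3130       0.12290398
#> 4       urban  50.8249       0.25692355
#> 5    excluded   0.0000               NA
#> 6       other   2.1180       0.01070664
```

197.8 km² of soil passes the rule; 57% of it is forested and only 4% is
open barren/shrubland/grassland — i.e. most of the edaphically suitable
land is candidate restoration area, not existing open habitat. Validation
against the held-out locations and the species occurrence groups:

```r
heldout <- scenario$locations
keep    <- heldout$data$location_id %in% fit$validation_ids
validation_report(map,
  heldout = vector_layer(heldout$geometry[keep], heldout$data[keep, , drop = FALSE]),
  species = scenario$occurrences)
#> ...
#> 59               mean over species summary      n/a 10    0.71
#> 60 mean over high-affinity species summary     high  5    0.77
```

High-affinity species groups overlap the map at 0.77 on this scenario —
close to their configured placement affinity, as they should.

`run_pipeline()` executes all of the above plus report writing and a
provenance sidecar in one call; `plot(fit)` draws the calibration scatter
with the thresholds.

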