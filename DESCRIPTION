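Package: edaphic
Title: Edaphic Habitat Suitability Modelling from Soil Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the edaphic (soil-driven) habitat of pine barren and
    sandplain ecosystems from gridded soil-survey data. Aggregates percent
    sand and depth to the nearest restrictive layer over the nested
    horizon/component/map-unit hierarchy of SSURGO-style soil surveys,
    calibrates suitability thresholds (area-weighted mean minus one
    area-weighted SD) from known ecosystem locations, classifies a landscape
    into suitable and unsuitable soils with wetland/open-water exclusion,
    summarises land cover on suitable soils, and validates the map by
    overlap with held-out locations and species occurrences. Includes a
    seeded synthetic soil-survey generator with ground-truth bookkeeping so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
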