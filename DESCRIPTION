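Package: mangresil
Title: Mangrove Ecosystem Assessment and Coastal Resilience Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for mangrove-ecosystem assessment:
    land-cover classification with random forests and accuracy assessment via
    the quantity-allocation disagreement index (QADI), two-epoch land-cover
    change accounting in hectares, canopy-height and aboveground-biomass
    estimation from a digital elevation model via allometric scaling,
    field-inventory biomass through three allometric models with wood-density
    handling, and a coastal exposure index (geometric mean of six ranked
    hazard variables) under habitat present/absent scenarios. A synthetic
    scene generator with controlled statistical structure replaces satellite,
    DEM and field data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
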