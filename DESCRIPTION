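Package: kelprf
Title: Benthic Habitat Classification from Bathymetry and Sea Surface
    Temperature with Monte Carlo Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying subtidal benthic habitats (bare substrate,
    kelp-dominated, mixed macroalgae, and red turf classes) from
    high-resolution bathymetry and satellite-derived sea surface temperature.
    Computes terrain predictors from a depth grid (Horn slope, aspect
    northness and eastness, Zevenbergen-Thorne mean curvature, vector
    ruggedness measure, and six-form geomorphons), composites cloud-masked
    thermal scenes into per-cell temperature statistics, screens predictors
    for collinearity, fits a Monte Carlo ensemble of random forests on
    repeated 70/30 splits of drop-camera ground truth, and maps per-cell
    ensemble votes into a nine-category confidence raster with percent-cover
    summaries. Includes a seeded synthetic-scene generator with a known
    habitat rule so the full pipeline is testable end to end without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
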