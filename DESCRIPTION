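Package: gridta
Title: High-Resolution Daily Air Temperature Modelling from Gridded Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts daily mean ambient air temperature on a fine regular grid
    (500 m cells) from sparse station observations and gridded spatiotemporal
    predictors such as reanalysis weather fields, satellite land surface
    temperature, topography and land use. Provides predictor derivation and
    harmonization to a common daily grid, station-grouped (leave-location-out)
    cross-validation, joint forward feature selection and hyperparameter grid
    search for a random-forest learner with a multiple linear regression
    baseline, full-grid prediction with monthly and annual aggregation,
    permutation feature importance on held-out stations, and a spatial/temporal
    decomposition of prediction error. A synthetic-world generator with a known
    data-generating process makes the whole pipeline testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
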