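Package: vinecast
Title: Vineyard Water Balance, Canopy Light Interception and Phenology Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sensor-less vineyard decision toolkit. Simulates diurnal solar
    position and clear-sky irradiance, models the row canopy as an opaque slab
    to derive total canopy light interception (TCLI) from its shadow footprint,
    fits intercept-free quadratic regressions of whole-canopy transpiration on
    direct light, vapour pressure deficit and TCLI, runs a daily soil-canopy
    water balance with stoplight drought warnings from a pedotransfer-derived
    soil reservoir, and predicts budburst, flowering and veraison dates with a
    windowed binary-event classification harness (feature screening,
    over/under-sampling, leave-one-out cross-validation, confusion-matrix and
    AUC metrics, RMSE-in-days scoring). Includes a seeded synthetic-data
    generator for weather, vineyard configurations, phenology events and
    transpiration observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    xgboost,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
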