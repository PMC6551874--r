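Package: migrasdm
Title: Seasonal Niche Models and Migration Analytics for Telemetered Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits presence/pseudo-absence boosted-tree ecological niche models
    from GPS telemetry and gridded environmental predictors, scores them to a
    regular 500-m grid as a relative index of occurrence (RIO), thresholds the
    surface at the error-minimising (sensitivity = specificity) cutoff, and
    derives migration analytics: annual predicted areas, deviations of mean
    seasonal positions, multi-year composite frequency maps of repeatedly used
    corridors, and land-cover selection ratios (use vs. availability). Includes
    a synthetic landscape and telemetry generator with known ground truth so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
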