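Package: flywayplan
Title: Full-Annual-Cycle Spatial Prioritization for Migratory Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing land conservation across the full annual
    cycle of migratory species. Estimates weekly relative-abundance surfaces
    from checklist-style observations with an ensemble of block-local
    zero-inflated models, partitions each species-week surface into regional
    abundance clusters with k-medoids (CLARA), builds and solves minimum
    set cover reserve-selection problems (integer linear programming) under
    weekly/yearly, single-population/clustered and uniform/human-footprint
    cost scenarios, and summarizes solutions by area, selection frequency,
    scenario agreement and land cover. A synthetic-landscape module generates
    migratory abundance cubes, checklist observations, cost surfaces and
    categorical land cover so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    xgboost,
    withr,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with SciPy (>= 1.9) on the PATH for
    exact integer-programming solves.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
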