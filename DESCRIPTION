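Package: aridrange
Title: Presence-Only Distribution Modeling for Arid-Climate Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for climate-hypothesis-driven presence-only species
    distribution modeling in arid mountain landscapes: spatial thinning of
    occurrence records, maximum-entropy (Maxent-style) suitability modeling
    with L1 regularization over sets of climate variables, spatially
    structured train/test evaluation (AUC, AICc, True Skill Statistic),
    nested suitability categorization of thresholded suitability surfaces,
    and Koppen-Geiger arid climate classification (BWk/BWh/BSk/BSh).
    Includes a synthetic landscape and occurrence generator emulating a cold
    arid mountain system so the full workflow runs without external data.
    Rasters are plain-text ESRI ASCII grids; points are CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
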