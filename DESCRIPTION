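Package: understoryHSM
Title: Demography-Based Habitat Suitability from LiDAR Understory Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and validate a habitat suitability model for an
    open-nesting boreal forest bird from demographic data. Computes a LiDAR
    understory-density metric (percentage of returns in a low vegetation
    stratum) on a regular grid, derives a nest-predator proximity proxy from
    the distance to human settlements, fits binomial mixed models of breeding
    success with crossed random intercepts (year and both breeder identities),
    selects the settlement-distance breakpoint and the understory transform by
    AICc, scans the spatial scale of effect across nest-centred radii, and
    extrapolates the fitted model to landscape rasters that are validated
    against independent occurrence maps. Includes a synthetic-scene generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
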