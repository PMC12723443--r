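Package: habistack
Title: Stacked Presence-Background Habitat Suitability Models, Richness
    Hotspots and Conservation Gap Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for flyway-scale habitat analysis
    from presence-only occurrence records: presence-background maximum-entropy
    suitability modelling with percent contribution, jackknife gains and
    replicate AUC evaluation; two-step predictor screening (zero-contribution
    removal and pairwise Pearson filtering at occurrence points); Fisher-Jenks
    natural-breaks binarization and stacking of per-species maps into richness
    and hotspot surfaces; group-level climate-driver importance via
    gradient-boosted trees with stratified cross-validation; a use-availability
    land-use preference index; moving-window Shannon diversity and evenness
    with disturbance-exposure profiling; and protected-area gap analysis by
    biogeographic region. Includes a synthetic landscape generator with known
    ground truth (correlated Gaussian random fields, terrain, land-cover
    mosaic, biased presence-only sampling) so every stage is testable without
    external data. Rasters are exchanged as ESRI ASCII grids; reserve and
    region polygons as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
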