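Package: firescape
Title: Historical Fire-Severity Regime Reconstruction from Tree Rings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs historical (pre-fire-exclusion) fire-severity regimes
    in montane forests from tree-ring fire-scar and age-structure data, and
    compares them with observed burn severity and modeled fire behavior.
    Provides readers for FHX2-style fire-scar chronologies and tabular tree and
    site data; coring-height and pith-offset age corrections; detection of
    spreading fires, composite fire chronologies and mean fire intervals;
    classification of individual fires as low, moderate or high severity from
    remnant-tree and establishment percentages; per-site fire-regime
    assignment; a classification-tree landscape model of regime as a function
    of terrain with cross-validated pruning; raster overlay comparisons against
    observed burn-severity classes and modeled fireline intensity and crown
    activity; and a stochastic generator of synthetic fire and stand histories,
    landscapes and severity rasters for end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
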