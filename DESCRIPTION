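Package: mangroveSDM
Title: Ensemble Species Distribution Modelling for Mangrove Bivalves Under
    Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for ensemble species distribution modelling of
    mangrove-associated species under current and future climate. Covers
    regression-kriging downscaling of coarse bioclimatic rasters with elevation
    as covariate, depth-weighted soil aggregation, surface-range-envelope
    (SRE) pseudo-absence design, cross-validated member classifiers combined
    into a TSS-weighted mean ensemble, KAPPA/TSS/AUC evaluation, maxSSS
    binarization, four-category range-change mapping with zonal area
    accounting, and centroid-based direction-of-shift analysis. Includes a
    synthetic-landscape generator with known niches and known future climate
    displacement so every stage has a recoverable ground truth, plus a minimal
    single-band GeoTIFF reader/writer and CSV occurrence I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    yaml,
    jsonlite
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
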