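Package: forestdyn
Title: Land-Cover Change, Forest Fragmentation and Transition-Risk Modelling
Version: 1.0.0
Authors@R: person("HRL", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for categorical land-cover change analysis of
    mountainous forest landscapes: classification post-processing (gap
    filling, elevation-band reassignment, majority filtering), error-adjusted
    accuracy and area estimation from stratified validation samples with 95%
    confidence intervals, pixel-by-pixel transition matrices and compound
    annual deforestation rates, multiscale forest area density (FAD)
    fragmentation with forest-interior delineation, and multinomial logistic
    transition-risk models fitted by repeated 10% subsampling with relative
    risk ratios. Includes a seeded synthetic-landscape generator with known
    ground-truth transition coefficients for end-to-end validation, a compact
    random-forest classifier, and plain-text raster (ESRI ASCII grid) and
    GeoJSON I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
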