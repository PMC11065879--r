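Package: phenomigrate
Title: Soybean Mapping by Phenology-Based Training-Sample Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates soybean and non-soybean training samples from satellite
    image time series without new field campaigns, by migrating a small set of
    reference soybean points across years and regions. Candidate cropland
    points are screened with a canopy-chlorophyll concavity index on the
    TCARI/OSAVI curve, then confirmed against two trivariate Gaussian models of
    growing-season curve integrals (a high-value group EVI/RE2/SWIR2 and a
    low-value group LSWI/RENDVI/REPI) via Monte-Carlo density thresholds and
    Mahalanobis-distance percentiles. The package also provides the
    surrounding mapping workflow: Sentinel-2-like spectral indices and
    Sentinel-1-like SAR parameters, temporal compositing, divided-difference
    gap filling and Savitzky-Golay smoothing, phenology extraction
    (SOS/POS/EOS), harmonic and statistical feature extraction with
    random-forest feature selection, random-forest classification with a
    tree-count selection protocol, eight-neighbourhood majority filtering, and
    confusion-matrix / area-agreement validation metrics, plus a synthetic
    multi-crop scene generator for testing every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    signal,
    randomForest,
    jsonlite,
    yaml,
    geosphere,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
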