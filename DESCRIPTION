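Package: peatluc
Title: Peatland Land-Use Mapping and CO2 Accounting from Multispectral
    Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for land-use mapping of
    degraded raised bogs from multi-temporal multispectral imagery and for
    tiered CO2-C emission accounting on the mapped areas. Provides a
    synthetic scene generator (seven-class LUCIP ground truth, ten-band
    reflectance signatures, cloud-contaminated scene series, training
    polygons), QA-bitmask cloud masking and temporal median compositing,
    NDVI/NDWI spectral indices, random-forest pixel classification with
    variable importance, stratified validation sampling with confusion-matrix
    accuracy statistics, good-practice area-based error matrices yielding
    unbiased class-area estimates with standard errors, zonal tabulation,
    and Tier-1/Tier-2 emission-factor accounting with uncertainty ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
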