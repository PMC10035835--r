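Package: kelpcanopy
Title: Kelp Canopy Area Dynamics from Multispectral Satellite Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates emergent kelp canopy area from multiband surface-reflectance
    scenes and analyses its multi-decade dynamics. Implements the full processing
    chain used for Landsat-based kelp monitoring: quality-band cloud masking,
    elevation and MNDWI intertidal land masking, band-normalized decision-tree
    pixel classification seeded by k-means clustering, multiple endmember spectral
    mixture analysis (MESMA) with a static kelp endmember and per-scene seawater
    endmembers, seasonal per-pixel statistics, grid-cell aggregation with explicit
    missing-data rules, annual-maximum and regional series, generalized least
    squares trend estimation with autoregressive errors selected by AIC, and
    marine-heatwave response and recovery metrics. A synthetic scene generator
    with known ground truth makes every stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
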