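Package: landcomp
Title: Spatially Weighted Landscape Composition Metrics for Catchment
    Water-Quality Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes thirteen landscape composition metrics that weight
    land-use proportions within headwater catchments by inverse Euclidean
    distance to the stream, inverse D8 flow-path length, slope gradient and
    (log-transformed) flow accumulation, and compares the metrics as
    single-predictor linear models of stream water-quality parameters.
    Includes the raster terrain toolchain the metrics require
    (priority-flood depression filling, D8 flow direction with flat
    resolution, flow accumulation, flow length, watershed delineation,
    Horn slope, Euclidean distance transform), an ESRI ASCII grid
    reader/writer, and a synthetic-catchment generator that produces
    drainable terrain, autocorrelated two-category land-use mosaics,
    stream networks and water-quality tables with a known generating
    metric, so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
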