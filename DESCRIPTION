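Package: cropwave
Title: Terrain-Dependent Dispersal Speeds of the Southwest Asian Crop Package
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates biome-dependent front speeds for the eastward dispersal
    of the southwest Asian Neolithic crop package (wheat and barley) from
    radiocarbon dates. Builds a friction surface over a terrain-class raster,
    accumulates least-cost distances from an origin site using a 16-direction
    (knight's move) stencil, predicts arrival times from a base front speed,
    and fits the per-class friction costs by minimising the root-mean-square
    error against median calibrated radiocarbon dates with a genetic
    algorithm.  Ships a radiocarbon calibration routine, a synthetic-data
    generator for parameter-recovery experiments, and an end-to-end pipeline
    with tabular and raster outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
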