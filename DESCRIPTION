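Package: habiquant
Title: Habitat-Quality Assessment, Hotspot Statistics and Driver Path Models for Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for habitat-quality assessment on categorical
    land-use grids. Implements a threat-based habitat degradation and quality
    model with distance-decay kernels (linear and exponential), land-use
    transition accounting between dates, global Moran's I and Getis-Ord Gi*
    hot/cold-spot classification, and covariance-based structural equation
    models of natural and anthropogenic habitat-quality drivers with
    direct/indirect/total effect decomposition. Ships a synthetic landscape
    and covariate generator emulating an east-forest / central-cropland /
    west-grassland plain so the full pipeline is testable without external
    rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
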