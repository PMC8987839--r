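Package: greenview
Title: Green View Index Estimation from Streetscapes with the
    Chopped-Picture Method
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patch-based estimation of the Green View Index (GVI) of
    street-level imagery. Rectangle annotations are chopped into small
    overlapping square patches (the chopped-picture method) that train a
    compact convolutional neural network; whole images are then scanned
    as a grid of non-overlapping cells and the GVI is the percentage of
    cells classified as greenery, aggregated to district level. Includes
    a seeded synthetic streetscape generator with ground-truth greenery
    masks, a colour-band-difference baseline classifier, a cell-wise
    evaluation protocol (accuracy, precision, recall), survey manifest
    filtering, district aggregation with GeoJSON export, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
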