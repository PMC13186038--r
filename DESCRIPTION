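Package: oasiscarbon
Title: Carbon Stock Accounting and Driver Detection for Arid Oasis Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for ecosystem carbon assessment in arid
    oasis landscapes. Provides chemometric sample partitioning (SPXY) and
    variable selection (Pearson screening, competitive adaptive reweighted
    sampling, iterative retained information variable selection), random
    forest and support vector regression inversion of aboveground biomass
    and soil organic carbon to rasters, four-pool carbon density assembly
    with climate-based temporal correction, InVEST-style carbon stock
    accounting with land-use-transition decomposition, and an
    optimal-parameters geographical detector (q statistic) for driver and
    interaction detection. Includes a seeded synthetic oasis scene
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
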