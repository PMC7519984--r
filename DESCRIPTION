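Package: mirheat
Title: Heat-Responsive miRNA-Target Regulatory Module Discovery from
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for discovering heat-responsive
    microRNA-target regulatory modules from paired miRNA/mRNA time-course
    microarray data, as used for rice post-meiosis panicles under heat
    stress. Implements detection-flag filtering, quantile normalization
    with baseline-to-median centering, per-timepoint differential
    expression against a time-zero control (plain or moderated t),
    miRNA-family direction aggregation, plant miRNA target-site
    prediction by expectation-penalty scoring with seed-region weighting,
    anti-correlated miRNA-family/target pairing, construction of a
    heterogeneous miRNA-PPI network with coregulatory module detection,
    GO-Slim and characterized-gene annotation summaries, and a fully
    seeded synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
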