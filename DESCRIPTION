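Package: mpmsen
Title: Senescence and Life-History Analysis of Clonal and Sexual Plants from
    Matrix Population Models
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative demographic analysis of senescence in
    clonally and sexually reproducing plants from stage-based matrix
    population models (MPMs). Decomposes projection matrices into survival
    (U), sexual recruitment (F) and clonal recruitment (C) components,
    derives age-from-stage life tables with seed-bank left-truncation and
    quasi-stationary right-truncation, computes Keyfitz life-table entropy
    and Demetrius reproductive entropy, assembles standardized life-history
    trait matrices with outlier masking and chained-equation imputation
    (predictive mean matching), performs phylogenetically corrected PCA
    under a Brownian-motion model, and fits the downstream regression and
    group-comparison models. A synthetic-data generator produces MPM
    collections with known mortality regimes (Type I/II/III survivorship),
    Yule trees and Brownian-motion traits so every pipeline stage is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
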