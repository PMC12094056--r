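Package: penmodel
Title: Genetic Analysis of Daily Milk Weights with Pen-Based Contemporary Groups
Version: 0.1.0
Authors@R: person("penmodel", "developers", role = c("aut", "cre"),
    email = "penmodel@example.org")
Description: Repeatability animal models for daily milk weights of dairy
    cows, with contemporary groups defined either as herd-year-season of
    calving (HYS) or herd-pen-milking date (HPM).  Provides pedigree
    relationship algebra (numerator relationship matrix, inbreeding,
    sparse inverse), data edits and contemporary-group construction,
    a single-site Gibbs sampler for location effects and variance
    components, heritability / repeatability / sire-reliability
    summaries, and a synthetic herd simulator with phenotype-driven pen
    reassignment for end-to-end testing without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
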