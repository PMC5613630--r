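Package: hordif
Title: Differential Item Functioning for Multilevel Polytomous Items by
    Ordinal and Hierarchical Ordinal Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects uniform and omnibus differential item functioning (DIF)
    in polytomously scored items when persons are nested in clusters
    (children in schools, patients in hospitals). Implements likelihood-ratio
    DIF tests under proportional-odds ordinal logistic regression (OLR) and
    under a random-intercept hierarchical ordinal logistic regression (HOLR)
    fitted by maximum marginal likelihood with adaptive Gauss-Hermite
    quadrature; a multilevel graded-response-model simulator with
    controllable intraclass correlation, balanced within- or between-cluster
    grouping, and injectable uniform DIF; a Monte-Carlo harness estimating
    Type I error and power over fully crossed factorial designs; and
    screening diagnostics (ordinal intraclass correlation, design effect,
    item characteristic functions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
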