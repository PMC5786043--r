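Package: popgrasp
Title: Population Analysis of Factorial Grasping-Task Spiking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing populations of (non-simultaneously recorded)
    single- and multi-units from delayed-grasping experiments with a factorial
    task design (hand x grip type x handle orientation). Provides an
    inhomogeneous-Poisson synthetic population generator with planted factorial
    structure, Gaussian-kernel firing-rate estimation in multiple event
    alignments, per-unit cluster-based permutation tuning tests with
    family-wise control over factors and time, demixed principal component
    analysis over task-factor marginalizations, a cross-dataset
    shared-component selection and back-projection procedure, and Monte-Carlo
    pseudo-trial decoding with shuffle-based chance distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
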