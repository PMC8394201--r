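Package: replifire
Title: Stochastic Modelling of DNA Replication Origin Firing and DNA Combing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic Monte Carlo simulation of DNA replication kinetics on a
    one-dimensional genome lattice under a family of nested limiting-factor
    models (MM1-MM5), as studied in Xenopus egg extracts. Includes emulation
    of single-molecule DNA combing observables (eye, gap and eye-to-eye
    length distributions, per-molecule firing rate and fork density curves),
    genetic-algorithm parameter inference against combing data, generation
    of ground-truth synthetic combing datasets, and replication-timing
    profiles segmented into constant timing regions (CTRs) and timing
    transition regions (TTRs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
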