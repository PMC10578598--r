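Package: metasweep
Title: Gene-Specific Selective Sweeps in Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic event-driven simulation and closed-form theory for the
    fate of metacommunity diversity when beneficial genes spread by migration
    (genome-wide sweeps) and by horizontal gene transfer (gene-specific
    sweeps). Implements a Hubbell-type infinite-allele neutral model of
    diversity maintenance over M patches, its Ewens-sampling-formula
    equilibrium analytics, the logistic fixation dynamics of a beneficial
    gene, the sweep parameter Q0 quantifying residual diversity after
    fixation, and the full competing-time-scales model with single, periodic
    or Poisson gene arrivals, together with ensemble replication utilities
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
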