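Package: cpmsort
Title: Connectivity-Preserving Cellular Potts Simulations of Cell Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates differential-adhesion-driven cell sorting in
    two-dimensional binary cell mixtures with a Cellular Potts Model whose
    Metropolis dynamics enforce a local connectivity test at every copy
    attempt, so cells can never fragment or become multiply connected.
    Provides lattice initialization (free aggregates in medium, periodic
    tilings), flood-fill connectivity audits, the standard sorting
    observables (heterotypic boundary length, spatial autocorrelation and
    its first zero as the cluster size, homotypic cluster counts), and
    scaling analysis utilities (log-log power-law exponent fits, master
    curve collapse, diffusion-coalescence theory predictions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
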