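Package: signoise
Title: Noise, Output Range, and Information Acquisition in Stochastic
    Signaling Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of reversible
    molecular binding, consecutive binding cascades, transcription-factor
    regulated gene expression (with and without polymerase-mediated
    extrinsic noise), and a complete linear signaling pathway.  The
    package quantifies how binding affinity shapes the mutual information
    between a signal and a pathway output, the expression noise (average
    Fano factor of the response distributions), and the output range,
    across affinity and concentration sweeps.  An exact stationary
    distribution of the reversible-binding birth-death chain serves as an
    analytic oracle for the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
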