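Package: conndyn
Title: Personalized Brain Network Models on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates delay-coupled Wilson-Cowan neural-mass dynamics on
    subject-specific weighted structural connectomes and links individual
    network dynamics to behavior. Provides a global-coupling sweep that
    detects each subject's excitability transition value, an in-silico
    stimulation protocol with maximum-lagged-cross-correlation functional
    connectivity and circuit-resolved functional effects, graph-spectral
    network statistics, bootstrap Pearson correlation with false discovery
    rate control, randomization controls (edge-weight shuffling, random
    subnetworks, alternate stimulation sites), and a synthetic-cohort
    generator for end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    nortest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
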