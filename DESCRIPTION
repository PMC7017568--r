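Package: spikegc
Title: Identifying Spiking Neural Network Structure by Nonlinear Granger
    Causality
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates leaky integrate-and-fire spiking neural networks with
    known, randomly generated directed connectivity and identifies that
    connectivity back from the simulated multichannel spike trains by
    conditional Granger causality. Two identification methods are provided:
    a linear vector-autoregressive test (LGCIM) and a nonlinear test in which
    each channel's lagged past is expanded in radial basis functions fitted
    by k-means clustering, a nearest-neighbour width rule and minimum
    square error weights (NGCIM; Gaussian, reflected-sigmoidal and
    inverse-multiquadric kernels). A batch experiment driver runs the whole
    generate-simulate-identify-score protocol and reports ordered-pair
    identification accuracy against the ground-truth adjacency matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
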