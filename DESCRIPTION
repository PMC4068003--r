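Package: neurocrit
Title: Neuronal Avalanche Statistics, Criticality Analysis and Spiking-Network Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate self-organized critical, driven-critical,
    driven-subcritical and Poisson regimes of neural population activity.
    Provides fast simulators for a modified Bak-Tang-Wiesenfeld lattice of
    non-leaky integrate-and-fire neurons and for a stochastic branching
    network, in separation-of-time-scales or Poisson-driven mode; subsampling
    of spike rasters; bin-size-dependent avalanche statistics (size
    distributions, mean size, frequency of size-one avalanches, the bin-ratio
    branching-parameter estimator); detrended fluctuation analysis; maximum
    likelihood fitting and comparison of heavy-tailed avalanche-size
    distribution families; and extraction of binary events from continuous
    field-potential traces by the positive-deflection-area method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
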