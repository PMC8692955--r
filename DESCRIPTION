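Package: cpfnet
Title: Central-Place Foraging Networks and Information Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of central-place foraging on patchy,
    power-law resource landscapes, extraction of the weighted co-location
    interaction networks that emerge between foraging units, weighted
    global and local network efficiency, Louvain subgroup structure, and
    simple/complex contagion simulations of information transmission on
    those networks.  Includes factorial parameter sweeps over environmental
    heterogeneity, foraging radius and population size.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
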