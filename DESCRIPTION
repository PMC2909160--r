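Package: frustral
Title: Frustration and Energy-Landscape Analysis of Signed Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how far a signed molecular interaction network
    (activation/inhibition edges) is from a monotone system. Implements the
    frustration index of a signed graph via gauge (switching) transformations,
    exact enumeration for small graphs and a seeded simulated-annealing
    heuristic for larger ones, sign-reshuffling null models and sign-packing
    statistics, exact Boltzmann thermodynamics and a frustration-corrected
    heterogeneous mean field parametrized by the interaction strength beta,
    Metropolis sampling, and a census of the energy landscape (local and
    global minima, Hamming-distance histograms, inter-minimum trajectories
    and average gradient profiles). Includes generators for synthetic signed
    networks with transcriptional- or metabolic-like structure and the
    classic 11-node yeast cell-cycle network as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
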