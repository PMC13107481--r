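Package: mecnonlocal
Title: Nonlocal Spatial Coding Analysis for Entorhinal Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting and characterizing nonlocal
    spatial coding in medial entorhinal cortex (MEC) population activity on a
    linearized X-maze. Implements a switching-dynamics Bayesian state-space
    position decoder (stationary / continuous / fragmented latent dynamics) with
    a naive-Bayes validation decoder, track-graph linearization and chance-level
    geometry, immobility and nonlocal-bout detection, shuffle-based single-unit
    statistics (linear fields, preferential recruitment, grid / border / head
    direction / speed / reward cell classification), sharp-wave-ripple detection
    from CA1 LFP and multi-unit activity, MEC-CA1 spike-timing coordination, and
    trial-accuracy prediction from nonlocal content. A synthetic-session
    generator with known ground truth (place fields, injected remote
    reactivation events, lag-coupled CA1 spiking, ripple-bearing LFP) makes
    every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
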