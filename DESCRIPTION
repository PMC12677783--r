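Package: netreconfig
Title: Dynamic Brain-Network Reconfiguration from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Maintainer", "netreconfig", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs time-varying functional brain networks from
    multichannel electrophysiological recordings and quantifies their
    reconfiguration. Band-limited signals (Butterworth decomposition after
    notch and high-pass preprocessing) are segmented into non-overlapping
    windows; phase-locking value (PLV) connectivity per window yields a
    multilayer network per subject and frequency band. Communities are
    detected per layer with a seeded Louvain algorithm, validated against
    degree-preserving weight-shuffled surrogate nulls, and regularized over
    time by multilayer modularity with ordinal inter-layer coupling.
    Node- and community-level reconfiguration metrics (flexibility,
    cohesion strength, disjointedness, community cohesion, community
    disjointedness, community change) feed Kruskal-Wallis group statistics
    with FDR-corrected post-hoc comparisons and a six-classifier benchmark
    with repeated matched subsampling. A synthetic oscillatory-cohort
    generator with planted community schedules and group coupling deficits
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    FNN,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
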