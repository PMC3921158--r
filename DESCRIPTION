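Package: plinet
Title: Phase Lag Index Connectivity and Weighted Brain Network Analysis of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phase lag index (PLI) and directed PLI functional
    connectivity from multichannel resting-state EEG, per canonical frequency
    band, together with weighted graph metrics (mean weighted clustering
    coefficient, characteristic path length via Dijkstra shortest paths on
    inverse-PLI distances) normalized against edge-shuffled surrogate
    networks, and a small-world index. Includes a seeded coupled-oscillator
    simulator that generates multichannel EEG-like cohorts with known
    band-specific phase-lag coupling and zero-lag mixing (volume conduction),
    group-level statistics (log-transformed pooled t-tests with partial eta
    squared, PLI-power correlation, a-priori power analysis), readers and
    writers for ASCII epoch exports and EDF, and an end-to-end pipeline
    driven by a declarative configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
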