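Package: tumorca
Title: Stochastic Cellular-Automaton Tumor Growth Simulation with
    Seam-Based Parallel Stepping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates avascular tumor growth on a 2-D lattice with a
    stochastic cellular automaton in which each tumor cell dies, stays
    quiescent, proliferates by mitosis, or migrates to a free neighboring
    site at every step. Live cells are kept on active-cell lists (a
    two-list scheme) so work scales with the tumor, not the lattice. The
    package provides a sequential list-based engine, a naive full-grid
    oracle engine for equivalence testing, and a phase-ordered parallel
    engine that decomposes the lattice into horizontal regions separated
    by seams, processes bottom seams, centers, and top seams in barrier-
    separated phases so that no two workers ever write the same cell
    list, and rebalances load by displacing seams in a three-phase
    protocol when adjacent regions' cell counts diverge beyond a
    threshold. Includes configuration I/O, metrics and snapshot writers,
    parameter-sweep drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
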