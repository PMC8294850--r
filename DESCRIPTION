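Package: labmaze
Title: Analysis of Rodent Exploration in a Binary-Tree Labyrinth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the behaviour of mice exploring a binary-tree
    labyrinth from discretised trajectories. Builds the maze as a graph with a
    planar H-tree embedding and its symmetry operations; reduces continuous
    nose-keypoint tracks to node sequences and bouts; segments behaviour into
    drink/leave/explore modes with ethogram summaries; estimates cage-maze
    transition hazard rates; quantifies exploration efficiency from end-node
    discovery curves; estimates the four turning biases at T-junctions;
    simulates unbiased, biased, Markov and optimal exploration agents; detects
    sudden behavioural changepoints by inhomogeneous-Poisson maximum
    likelihood; and fits fixed- and variable-depth Markov models of junction
    decisions scored by cross-validated cross-entropy. Includes a synthetic
    session generator with full ground truth so every stage is testable
    without tracking data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
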