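Package: minibrains
Title: Minimal Evolutionary-Robotics Models of Neural Complexity in
    Social Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates embodied circular agents controlled by small
    continuous-time recurrent neural networks (CTRNNs) that interact
    through attenuated acoustic signals in an open two-dimensional arena.
    Agents are evolved with a real-valued genetic algorithm to maximize
    the normalized multi-dimensional Shannon entropy of their neural
    outputs, either alone (individual evolution) or as a co-evolved
    interacting pair (social evolution). Includes nonlinear time-series
    tools - embedding delay from the first minimum of time-lagged mutual
    information and embedding dimension from the false-nearest-neighbour
    method - for measuring the effective degrees of freedom of evolved
    neural activity, together with the balanced two-way ANOVA and
    Bonferroni post-hoc comparison used to contrast brain sizes and
    social conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
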