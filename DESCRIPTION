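Package: coopspaces
Title: Strategy Spaces in Evolutionary Game Models of Cooperation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of strategy space shapes the
    evolution of cooperation. Implements deterministic replicator dynamics
    and stochastic finite-population imitation dynamics with an exponential
    payoff-to-fitness mapping, exact fixation probabilities and
    small-mutation-limit stationary distributions, together with three case
    studies: the repeated prisoner's dilemma with reactive strategy sets of
    different sizes, the optional public goods game with a systematically
    constructed punishment strategy space, and indirect reciprocity with
    exogenous or endogenous second-order social norms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
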