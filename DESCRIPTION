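Package: netbehav
Title: Stochastic Actor-Based Co-Evolution of Friendship Networks and
    Adolescent Alcohol Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits stochastic actor-oriented models (SAOMs) for the joint
    evolution of a directed friendship network and an ordinal behavior
    (alcohol-use frequency) observed in two-wave school panels.  Provides
    the effect catalog for network selection (density, reciprocity,
    transitive triplets, 3-cycles, degree effects, covariate ego/alter/
    similarity/same effects) and behavior change (shape effects, average
    friend behavior, covariate effects), continuous-time micro-step
    simulation of the co-evolution process, Method-of-Moments estimation
    by Robbins-Monro stochastic approximation with convergence
    diagnostics, Snijders-Baerveldt and Fisher-combination meta-analysis
    across schools, and a calibrated synthetic multi-school panel
    generator for method validation when restricted survey data are
    unavailable.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
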