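Package: fluxorder
Title: Flux Order Relations and Hierarchies in Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact identification of flux-ordered reaction pairs in
    constraint-based metabolic models: pairs of reactions whose steady-state
    fluxes satisfy v_i >= v_j over the entire flux polytope. Ratio extrema are
    computed by linear-fractional programming via the Charnes-Cooper
    transformation, with a hit-and-run sampling prefilter and flux-coupling
    analysis (full, partial, directional) for candidate pruning. The induced
    partial order is assembled into a transitively reduced directed acyclic
    graph with hierarchy levels, biomass-ancestor and reaction-essentiality
    analyses, and concordance statistics (mean data differences, positive
    fraction, permutation p-values) for testing whether omics profiles respect
    the predicted ordering. Reads SBML (Level 3 + fbc) and COBRA-JSON models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
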