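Package: lvlattice
Title: Multi-Species Lattice Contact Process and the Paradox of Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of competition for space among phytoplankton
    species as a multi-species contact process on a periodic square lattice,
    with nutrient-dependent logistic birth rates, under local (von Neumann) or
    global (random-pair) interaction. Includes the mean-field Lotka-Volterra
    ODE counterpart with equilibrium classification, extinction-threshold
    estimation, nutrient-sweep experiments that exhibit the paradox of
    enrichment (species richness peaks at low nutrient levels and collapses
    under eutrophication), adjacency/clumping statistics for lattice
    snapshots, and tidy tabular outputs with ggplot2 visualisation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
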