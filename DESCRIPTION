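Package: pleioscope
Title: Machines Versus Ensembles in Rule-Based Models of Scaffold Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-free stochastic simulation and analysis of rule-based
    models of the yeast pheromone MAPK cascade. Provides a site-graph
    representation of molecular complexes with exact canonicalization, a
    Kappa-style rule dialect with parser and pattern-embedding semantics, a
    Gillespie direct-method simulator that samples the full combinatorial
    space of complexes, and programmatic builders for a scaled-down
    "ensemble" model (unordered scaffold assembly) and a "machine" model
    (hierarchical assembly of a decameric scaffold complex). Analyses
    include compositional drift (Jaccard distance between per-cell complex
    sets), autodrift with double-exponential relaxation fits, structural
    conservation and clustroid-based hierarchical clustering on graph edit
    distance, in-silico TAP/MS with socio-affinity scoring and Markov
    clustering, exact reachable-species enumeration, and the scaffold
    overexpression experiment probing combinatorial inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
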