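Package: micca
Title: Parameter Similarity and Identifiability Analysis for ODE Models
    via Canonical Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies similarity between groups of parameters of ordinary
    differential equation models of biochemical dynamics. Sensitivity vectors
    of observed trajectories are computed by forward sensitivity analysis;
    canonical correlations between the subspaces they span are mapped to an
    asymptotic mutual information between estimator blocks (MI-CCA). The
    package provides a (delta, zeta)-identifiability test for individual
    parameters, a modified agglomerative clustering that visualises
    compensatory parameter structure and returns an identifiable parameter
    set, and an experiment-screening utility that ranks candidate
    perturbations by the number of parameters they render identifiable.
    Models and experiments are declared programmatically or through a YAML
    configuration; built-in fixtures include a two-state gene expression
    model and a kinase activation sub-model with genetic perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
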