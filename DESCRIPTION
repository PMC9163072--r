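Package: signalnet
Title: Prior-Knowledge-Constrained Recurrent Models of Intracellular Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intracellular signal transduction as a sparse recurrent
    neural network whose connectivity is fixed by a prior-knowledge signaling
    network. Ligand concentrations are projected onto receptor nodes, the
    network state is iterated to a steady state under a Michaelis-Menten-like
    activation function, and transcription factor activities are read out from
    the converged state. Provides steady-state backpropagation for parameter
    fitting, spectral-radius regularization that keeps every training condition
    stable, automatic reference-model parameterization for synthetic
    ligand-to-TF datasets, and in-silico knockout, knock-in, and sensitivity
    analyses of trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    igraph,
    deSolve
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
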