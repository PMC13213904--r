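Package: kinscape
Title: Markov State Modelling and Cryptic-Pocket Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for analysing the conformational landscape of a single
    protein domain from coordinate ensembles: geometric featurization
    (side-chain centre-of-mass and C-alpha distances, backbone torsions,
    ring-plane angles), slow-mode estimation by time-lagged independent
    component analysis (TICA) with correlation-based feature ranking and
    redundancy/locality pruning, VAMP-2 scoring of candidate representations,
    microstate Markov state model estimation with reversible maximum
    likelihood and Bayesian posterior sampling, hidden-Markov coarse-graining
    into metastable macrostates with Chapman-Kolmogorov validation,
    transition-path-theory committors, reactive fluxes and pathway
    decomposition, per-state structural characterization (hydrogen bonds,
    secondary structure, RMSF, radius of gyration), and alpha-sphere cryptic
    cavity detection with frequency-grid isovalue selection and hydrophobic
    density scoring.  A synthetic-data module generates feature trajectories
    from a ground-truth hidden six-state chain and ideal structure fixtures so
    that every stage is testable against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
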