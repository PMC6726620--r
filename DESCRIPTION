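Package: tweezfold
Title: Single-Molecule Optical Tweezers Analysis of Protein Folding and
    Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule optical tweezers force
    spectroscopy of multi-domain proteins, motivated by studies of the
    cAMP-dependent protein kinase A regulatory subunit. Provides kinetic
    Monte-Carlo simulation of force-ramp and force-clamp trajectories with
    worm-like-chain serial compliance, rip detection in force-extension
    curves, contour-length-change estimation, transformation of rupture-force
    histograms into force-dependent lifetimes with Bell and
    Dudko-Hummer-Szabo model fits, Bayesian two-state hidden Markov analysis
    of constant-force hopping traces, global fitting of a sequential
    cooperative two-site ligand-binding model to single-molecule titration
    counts, equilibrium free-energy dissection, and residue contact-map
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
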