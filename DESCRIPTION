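Package: enmpipe
Title: Conformational Ensemble Generation by Iterative Elastic Network
    Model Sampling, Clustering and Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates conformational ensembles of biomolecules from a single
    input structure by iterating three steps: deformation of the structure
    along random linear combinations of the softest anisotropic network model
    (ANM) normal modes, hierarchical clustering of the resulting conformers by
    pairwise superposed C-alpha RMSD with medoid representative selection, and
    structural relaxation of the representatives.  Relaxation is a pluggable
    backend; a dependency-free geometric minimizer ships built in and an
    external molecular dynamics engine can be registered through the same
    contract.  Includes ensemble analysis tools (essential-dynamics PCA,
    projections, Gaussian kernel density population maps, inter-domain
    angles), PDB and DCD trajectory output, deterministic seeding, and
    synthetic toy-structure generators so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
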