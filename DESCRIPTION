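Package: crypticfold
Title: Unfolding Kinetics, Markov State Models and Cryptic
    Aggregation-Prone Regions in Stabilized Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the stability-solubility trade-off of
    engineered proteins. Implements global fitting of multi-technique
    thermal denaturation data (DSC, nanoDSF barycentric mean, CD,
    isothermal traces) to a three-state irreversible unfolding model
    under kinetic control, Markov-state-model assignment of folded,
    intermediate and unfolded ensembles from C-alpha RMSD feature
    series, per-residue solvent-accessibility (Shrake-Rupley SASA and
    relative SASA) exposure-change detection between conformational
    states, and segmentation of aggregation-score profiles into
    aggregation-prone regions with cryptic-APR flagging and
    mutation-level surface-hydrophobicity accounting. A synthetic-data
    module generates every input class with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
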