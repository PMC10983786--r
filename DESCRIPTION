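Package: remsuper
Title: Multilevel Superposition and Covariance Estimation for Protein
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous rigid-body superposition and covariance estimation
    for groups (ensembles) of protein conformations under a two-level
    random-effects model. Conformations are modelled as a population mean
    structure plus a per-ensemble deviation with inter-ensemble covariance W
    and a per-conformation deviation with intra-ensemble covariance Sigma,
    both full 3n x 3n anisotropic matrices estimated by an
    expectation-maximization algorithm with empirical-Bayes ensemble
    deviations. Heteroscedastic iteratively weighted least-squares (IWLS),
    two-stage and single-pooled-ensemble baselines are included, together
    with principal component analysis of the estimated covariance matrices
    (projections, per-residue displacement profiles, extreme structures,
    RMSIP subspace overlap), a synthetic multi-ensemble generator and a
    recovery-evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
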