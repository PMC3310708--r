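Package: hingescan
Title: Quasi-Rigid Domain Decomposition and Hinge-Axis Detection for
    Protein Calpha Trajectories
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale analysis of protein internal dynamics from Calpha
    coordinate trajectories. Computes superposition-free distance-fluctuation
    matrices and per-residue geometric strain profiles, decomposes a
    trajectory into quasi-rigid domains by stochastic minimisation of the
    per-frame rigid-body (Kabsch) fit error, and models side-domain motion as
    pure rotation about a time-independent hinge axis anchored on a Calpha.
    Trajectories of homologous proteins can be combined into a
    meta-trajectory of corresponding residues for one joint decomposition.
    Ships a synthetic-trajectory generator with planted rigid bodies, hinge
    axes and coordinate noise for validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    cluster,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
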