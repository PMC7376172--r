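Package: helix2beta
Title: Sequence and Coarse-Grained Trajectory Analysis of Helix-to-Beta
    Transitions in Amyloidogenic Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating the "hot" segments that open first when a
    helical amyloidogenic protein (such as alpha-synuclein) converts to
    extended, beta-prone conformations.  Implements Chou-Fasman style
    secondary-structure propensity estimation from annotated sequence sets,
    sliding-window sequence scans (beta-propensity chameleon regions,
    Roseman hydropathy cores, glycine-valine sites, valine-to-alanine
    scanning), a coarse-grained dihedral-space targeted molecular dynamics
    simulator with a harmonic RMSD restraint on a linearly decreasing
    reference, residue-by-frame kymograph metrics (local RMSD, change in
    radius of gyration, backbone hydrogen-bond counts) with hot-site
    detection and priority ordering, and dihedral principal component
    analysis with density peak-picking clustering and cluster
    representatives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    bio3d,
    seqinr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
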