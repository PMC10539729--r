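Package: ccecho
Title: Cluster-Correlation Expansion Simulation of Electron Spin Echo Decay
    in Nuclear Spin Baths
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates Hahn and refocused electron spin echo decays of dilute
    paramagnetic centres in protonated glassy matrices by fully coherent
    density-matrix propagation within a cluster-correlation expansion (CCE)
    over the nuclear spin bath.  Builds point-dipole hyperfine and nuclear
    dipolar couplings from geometry (synthetic baths or XYZ/PDB coordinates),
    performs Lebedev powder averaging, computes the second-order
    linked-cluster factorization of the refocused echo, extracts the ridge of
    optimal interpulse delays from two-dimensional decay maps, and fits
    stretched-exponential phase-memory decays.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
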