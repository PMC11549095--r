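Package: zipmtd
Title: Well-Tempered Metadynamics and Structural Analysis for an
    Elevator-Type Metal Transporter Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale reimplementation of the enhanced-sampling and
    structural analyses used to study metal release through an elevator-type
    ZIP-family zinc transporter. Provides a coarse-grained transporter
    landscape with planted metal-binding sites (M1, M2, M3), cytoplasmic
    release channels and a brute-force Boltzmann free-energy oracle;
    spherical and coordination-number collective variables with analytic
    gradients; overdamped Langevin dynamics with steered pulling;
    from-scratch well-tempered metadynamics with hill bookkeeping and
    PLUMED-style text I/O; free-energy-surface reweighting, basin detection,
    minimax pathway extraction; rigid-body hinge plus vertical-sliding
    decomposition of domain motion; and a four-scenario release-route
    pipeline with geometric route classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
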