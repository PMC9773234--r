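Package: granulocell
Title: Cell Fate on Free-Packed Microsphere Beds by Hybrid Particle Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid particle-based simulator of an adherent cell on a granular
    bed of microspheres. Settles polydisperse beds with a discrete element
    method (hysteretic Walton-Braun contacts, fourth-order Gear
    predictor-corrector), models the cell as a hexagonal network of sphere
    elements joined by viscoelastic springs that spreads through cycles of
    stretching and contraction, and implements three adhesion mechanisms:
    instantaneous integrin binding on contact, talin-like reinforcement above
    a force threshold, and detachment beyond a fractional contraction
    distance. Provides sweep drivers over cell-to-particle aspect ratio,
    particle density and bed depth, and the volume-ratio cell-fate statistic
    with plotting and tidying helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
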