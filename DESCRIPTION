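Package: morphofrill
Title: Morphoelastic Finite-Element Simulation of Neck-Frill Ridge Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tetrahedral finite-element simulation of frustrated homogeneous
    tissue growth in the embryonic neck frill of the frilled dragon
    (Chlamydosaurus kingii). Implements neo-Hookean hyperelasticity with
    multiplicative growth tensors, traction-based nodal forces, damped
    second-order dynamic relaxation, static and quasi-static growth drivers,
    parametric single-sheet and bilayer (skin-on-substrate) geometries,
    morphometrics of the resulting elastic wrinkling instability (ridge
    counts, amplitudes, wavelengths), and the two-layer depth-dependent
    nanoindentation model used to estimate the skin-to-substrate stiffness
    ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
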