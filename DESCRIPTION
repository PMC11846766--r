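Package: ossiforge
Title: Continuum-Based Particle Simulation of Endochondral Ossification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A continuum-based particle model of endochondral ossification in a
    developing long bone. Material points carrying a multiplicative
    elastic-growth deformation gradient are coupled to a background grid
    (material point method with quadratic B-spline interpolation) for
    quasi-static neo-Hookean mechanics, to a reaction-diffusion solver for
    Ihh and PTHrP morphogen signaling, and to an agent-based cell-cycle and
    differentiation engine. Drivers reproduce primary and secondary
    ossification of a distal metatarsal capsule, growth-plate zone metrics,
    fusion and resting-zone penetration detection, and maturation-rate
    sweeps of resting-zone PTHrP expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
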