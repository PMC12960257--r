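Package: dipidr
Title: Design and Analysis of Lipid-Inspired DNA Origami Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing membranes self-assembled from
    radially symmetric DNA origami monomers ("Dipids"). Converts target
    membrane curvatures into binding-strand length sets via a worm-like-chain
    polymer model and a geometric cone model, enumerates and exports monomer
    designs, and calibrates naive diameter predictions against measurements.
    Includes a bead-spring growth simulator for triangulated elastic shells
    that reproduces the cone-angle-controlled container/tube morphology
    transition, morphometry of collapsed container projections (ellipse
    fitting and circumference-preserving 3D reconstruction), largest
    inscribed-circle pore analysis of monomer lattices, two-channel membrane
    purity profiling, and seeded synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    EBImage,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
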