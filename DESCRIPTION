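Package: hingescan
Title: Hinge-Residue Detection from Coarse-Grained Normal Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies hinge residues governing interdomain motion in
    protein structures from a C-alpha elastic network model. Builds a
    secondary-structure- and disulfide-aware spring network, solves for
    normal modes, profiles per-residue deformation energy and atomic
    fluctuation, calls hinge regions where deformation is high but
    fluctuation low, excludes residues inside secondary-structure
    elements, measures hydrogen-bond persistence along mode-interpolated
    conformations, and cross-validates against principal component
    analysis of conformational ensembles. Includes seeded synthetic
    generators (ideal helices, two-domain dumbbells with a known linker,
    mode-sampled trajectories) so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
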