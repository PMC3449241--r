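Package: hexstim
Title: Hexahedral Finite-Element Simulation of Transcranial Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasistatic finite-element modelling of transcranial direct and
    alternating current stimulation (tDCS/tACS) on multi-compartment head
    models. Generates voxelized layered-sphere head phantoms with six tissue
    classes, optional gyral ridges and white-matter anisotropy; builds
    geometry-adapted hexahedral meshes; assigns isotropic or effective-medium
    conductivity tensors; assembles and solves the Laplace equation for the
    electric potential under inhomogeneous Neumann current injection through
    saline electrode patches; and post-processes current-density and
    electric-field distributions into tissue-wise statistics and montage
    focality comparisons. An analytic multi-layer concentric-sphere series
    solution is included as an independent correctness standard for the
    numerical solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
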