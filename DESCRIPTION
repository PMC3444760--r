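Package: ctcflow
Title: Immersed-Boundary Simulation of Circulating Tumor Cells in
    Microvessel Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-dimensional immersed-boundary model of a deformable
    circulating tumor cell traveling through a microvessel. The cell actin
    cortex and nuclear envelope are cross-linked Hookean spring networks,
    the endothelial walls are tethered rigid spring meshes, and the blood
    plasma is an incompressible Newtonian fluid advanced with an FFT
    projection solver on a periodic grid. Dynamic cell-wall adhesive
    springs and adhesion-triggered local cortex softening reproduce the
    stages of the leukocyte-style adhesion cascade (floating, rolling,
    anchoring, crawling), with shape and motion metrics to quantify cell
    deformation and locomotion mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
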