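Package: bltrecon
Title: Bioluminescence Tomography Reconstruction with One-Dimensional
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation and learned reconstruction for
    bioluminescence tomography (BLT). Generates labeled tetrahedral
    tissue phantoms, solves the diffusion-approximation forward problem
    with the finite element method to obtain surface photon flux
    densities, synthesizes single- and dual-source training datasets by
    superposition, trains a compact one-dimensional convolutional
    network (and a multilayer-perceptron baseline) to invert the
    surface-flux-to-source mapping, and evaluates reconstructions with
    location error and Dice metrics stratified by source depth and
    separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
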