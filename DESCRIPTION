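Package: wormsight
Title: Map Single-Cell Gene Expression onto a 3D Model of the C. elegans Nervous System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless toolkit for overlaying neuron-class-resolved
    single-cell RNA-seq expression (CeNGEN-style thresholded matrices)
    onto a 3D anatomical model of the Caenorhabditis elegans
    hermaphrodite nervous system. Resolves neuron-class labels to the
    302 individual neurons, partitions neurons by multi-gene
    co-expression signatures, overlays ligand/receptor sender-receiver
    roles, colors and exports 3D scenes (OBJ/MTL, glTF 2.0, PLY),
    renders deterministic flat-shaded PNG images offscreen, and answers
    point-based neuron-identification queries. Ships a synthetic
    fixture generator (toy worm model plus expression tables) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    utils,
    stats,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
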