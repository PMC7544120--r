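Package: tadfold
Title: Chromatin Folding Coordinates and Free-Energy Landscapes from
    Single-Cell Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-cell chromatin-tracing data through a
    deep generative lens. Converts per-cell 3D probe coordinates into
    binarized contact matrices, trains a variational autoencoder on them,
    derives a one-dimensional folding coordinate from the latent space via a
    linear support-vector-machine boundary, and decomposes the free energy of
    domain formation into energetic and entropic contributions by
    reference-polymer subtraction. Includes a coarse-grained Langevin polymer
    simulator (28-bead reference homopolymer and a two-domain chromatin-like
    variant) used to validate the energy estimates against ground-truth
    interaction energies, plus a synthetic imaging-data generator so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
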