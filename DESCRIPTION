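Package: pocvae
Title: Generative Design of Shape-Persistent Porous Organic Cages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-component variational autoencoder (VAE) over a
    disassembled representation of porous organic cages (POCs): tri-topic
    vertex precursors and the reaction type are encoded categorically while
    the di-topic edge precursor is encoded as a SMILES token sequence with
    reactive-site placeholder tokens. The VAE is jointly trained with a
    semi-supervised shape-persistence predictor, and the learnt latent space
    is searched with random sampling, spherical interpolation and Bayesian
    optimisation. A heuristic filter cascade (validity, novelty, precursor
    validity, reaction-site count, graph symmetry) screens generated cages,
    and a metric suite reports validity, novelty, uniqueness, precursor
    validity and symmetry rates. Includes a synthetic cage-dataset generator
    for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    lhs,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
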