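Package: jtprop
Title: Junction-Tree Variational Autoencoder with Property-Guided Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode molecules as stacked junction-tree and molecular-graph
    latent embeddings with a variational autoencoder, reconstruct molecules
    from latent vectors by sequential tree decoding and scored fragment
    assembly, regress a scalar property (such as a HOMO energy) from the
    latent mean, and search the latent space for molecules with a target
    property value by gradient descent with optional decode/re-encode
    projection. Includes junction-tree decomposition of molecular graphs,
    cluster-fragment vocabulary construction, two-phase variational training,
    three encoder/decoder/regressor fine-tuning strategies, and a synthetic
    fixture generator with a deterministic surrogate property for desk-scale
    experiments. Molecule input and output is via SMILES, with OpenBabel
    (through ChemmineOB) providing canonicalization and format conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
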