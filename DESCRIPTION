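Package: nucmpnn
Title: Unified Inverse Folding for Protein, DNA and RNA Backbones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Backbone-conditioned nucleic acid sequence design and fixed-dock
    protein-DNA binding specificity prediction with a unified biopolymer graph
    neural network. Proteins, DNA and RNA are represented as residue graphs
    with radial-basis-function distance edge features over a shared backbone
    atom set; a message-passing encoder and a random-order autoregressive
    decoder predict categorical distributions over a 26-token alphabet (21
    protein, 5 shared nucleic tokens). Includes position probability matrix
    (PPM) loading, information-content-weighted Pearson alignment of motifs
    to structures, training targets with within-class label smoothing and
    specificity augmentations, token-budgeted batching, a CPU training loop
    with hand-written backpropagation, evaluation metrics (sequence recovery,
    PPM mean absolute error and cross-entropy, C1'-RMSD with superposition),
    and synthetic helix/motif fixture generators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
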