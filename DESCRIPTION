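Package: abtmpnn
Title: Atom-Bond Transformer Message-Passing Neural Network for Molecular
    Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a directed message-passing neural network for
    molecular property prediction that augments the bond-embedding phase
    with additive (global-context) self-attention over directed bonds and
    the atom-embedding phase with biased multi-head scaled dot-product
    self-attention, where each attention head receives one Z-score
    normalized, lambda-scaled inter-atomic matrix (adjacency, 3D distance,
    or Coulomb) as an additive pre-softmax bias. Includes SMILES
    featurization built on ChemmineR/OpenBabel, multi-task regression and
    classification training with masked losses and Adam, random and
    Bemis-Murcko scaffold splitting, fivefold cross-validation, Bayesian
    hyperparameter search, atom-level attention capture, and similarity-map
    visualization of per-atom attention contributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
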