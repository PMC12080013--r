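Package: fatetox
Title: Fragment-Attention Transformer with E(3)-Equivariant Graph
    Convolutions for Multi-Organ Molecular Toxicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-branch neural architecture for predicting binary
    toxicity endpoints from molecular structure. An atom-level branch and a
    fragment-level branch each pass a molecular graph through a
    graph-augmented multi-head self-attention transformer (attention mixed
    with row-normalised bond adjacency and a softmax-transformed 2D distance
    matrix) followed by E(3)-equivariant graph convolutions over 3D
    conformer coordinates. The fragment branch fuses three fragmentation
    views (BRICS, Bemis-Murcko scaffolds, and functional groups) by weighted
    summation, and the prediction head concatenates both branch embeddings
    with extended-connectivity fingerprints. Multiple toxicity tasks are
    trained jointly with masked binary cross-entropy and PCGrad gradient
    surgery; attention coefficients from the final transformer layer provide
    per-atom toxicophore highlighting. Molecule parsing, conformer
    embedding, fingerprints and substructure matching are delegated to the
    RDKit toolkit through the system Python interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
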