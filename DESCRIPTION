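Package: rmat
Title: Relative Molecule Self-Attention Transformer for Molecular
    Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Transformer encoder for small-molecule property prediction in
    which every attention head sees, for each atom pair, a learned projection
    of a relation embedding that concatenates graph-neighborhood order, bond
    features and a radial-basis encoding of the 3D inter-atomic distance with
    a smooth polynomial cutoff envelope. Includes self-attention pooling to a
    graph embedding, an optional physicochemical-descriptor block, masked
    atom-context and graph-level descriptor pretraining tasks, a
    learning-rate-only fine-tuning protocol with Bemis-Murcko scaffold
    splitting, and a deterministic generator of small drug-like fixture
    molecules. Molecule perception, conformer generation and descriptors are
    delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit importable, found as
    'python' on the PATH or via the RMAT_PYTHON environment variable.
Config/testthat/edition: 3
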