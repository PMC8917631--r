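Package: moltriplet
Title: Deep Metric Learning for Molecular Graph Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds scaffold-aware training triplets from SMILES collections
    (standardization and structural filters, pharmacophore reduced graphs,
    Bemis-Murcko graph and detailed frames, cluster-based anchor/positive/
    negative sampling), trains a message-passing graph neural network with
    the triplet margin loss to obtain a Euclidean molecular similarity
    embedding, and evaluates the embedding against circular-fingerprint
    Tanimoto baselines (triplet ordering, distance distributions, deletion
    robustness, and a statistically tested k-nearest-neighbour activity
    benchmark). Ships a deterministic synthetic scaffold-library generator
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    Matrix,
    class,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
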