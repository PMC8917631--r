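# moltriplet

Deep metric learning for molecular graph similarity, end to end in R.

Medicinal and computational chemists usually quantify "how similar are these
two molecules?" as a Tanimoto coefficient over hashed circular fingerprints
(ECFP4). That metric has known blind spots: repeated motifs saturate the bit
set, small scaffold edits that reshuffle fragment hashes look enormous, and
partial or chemically invalid graphs have no meaningful fingerprint at all.
`moltriplet` builds the alternative: a message-passing neural network (MPNN)
trained with the triplet margin loss

```
L(a, p, n) = max(0, ||z_a - z_p|| - ||z_a - z_n|| + margin)
```

so that Euclidean distance between learned 16-dimensional embeddings
`z = MPNN(molecular graph)` acts as a similarity metric. Training triplets
come from structure alone: molecules sharing a pharmacophore **reduced
graph** (RG) and a Bemis-Murcko **graph frame** (GF) form GFRG clusters;
an anchor and its positive are drawn from one cluster, and the negative
from a *different* cluster under the *same* reduced graph — similar enough
to be a hard example. The package covers the whole workflow:

* `standardize_collection()` / `filter_collection()` — parent-structure
  extraction, charge neutralization, valence/isotope/element/weight checks,
  REOS and PAINS-A substructure alerts (shipped as versioned SMARTS assets).
* `key_set()` — reduced-graph, graph-frame and detailed-frame keys.
* `build_clusters()`, `assign_centroids()`, `identity_filter()`,
  `prune_single_cluster_rgs()`, `sample_triplets()` — the cluster rules
  (minimum size 4, DFRG switch at 10k, cap at 20k, ECFP4 identity ratio
  0.4, two-clusters-per-RG) and seeded triplet sampling.
* `train_embedder()`, `embed_graphs()` — featurization, node/edge ablation
  regularization (1% / 5%), Adam, early stopping, all in plain matrix
  algebra on sparse block-diagonal batches.
* `compare_orderings()`, `distance_distributions()`, `deletion_probe()`,
  `knn_benchmark()` — the evaluation probes, with Cohen's kappa,
  Cochran's Q and exact McNemar tests implemented and oracle-verified.
* `generate_library()` / `generate_activity()` — a deterministic synthetic
  scaffold library (~2,350 molecules in reduced-graph-paired families) and
  activity tables, so everything runs without external data.

Chemistry primitives (canonical SMILES, molecular graphs, ECFP0/ECFP4,
SMARTS matching, neutralization) are backed by OpenBabel through
`ChemmineOB` and the `obabel` executable.

## Worked example

```r
library(moltriplet)

lib <- generate_library()                 # 2,353 unique molecules
ds  <- build_triplet_dataset(lib$canonical_smiles,
                             sampling_config(triplets_per_cluster = 12))
nrow(ds$triplets)                         # 1836 triplets, 153 clusters

fit <- train_embedder(ds$triplets,
                      train_config(max_epochs = 60,
                                   early_stopping_patience = 15))

# held-out triplets: a fresh seeded draw, training tuples removed
ev <- sample_triplets(ds$clusters,
                      sampling_config(triplets_per_cluster = 3,
                                      rng_seed = 271828))
ord <- compare_orderings(fit$model, ev)
unlist(ord$summary)
#>               n  n_both_correct  n_fp_only_fail n_emb_only_fail
#>             436             356              80               0
#>     n_both_fail      n_ties_emb       n_ties_fp
#>               0               0               6
```

Read: of 436 held-out triplets the trained embedding orders every one
correctly (positive strictly closer to the anchor than the negative), while
ECFP4 Tanimoto dissimilarity fails on 80 — the embedding keeps working where
fragment hashing misleads. The distance distributions separate accordingly
(`distance_distributions()`: mean anchor–positive 2.49 vs anchor–negative
12.68, one-sided rank-sum p < 1e-100), and deleting 0–10 random graph
elements moves a molecule's embedding almost linearly away from the
original (`deletion_probe()`: Spearman rho 0.90, distance exactly 0 at zero
deletions) — fingerprints cannot even be computed on most of those
mutilated graphs. On synthetic activity targets whose labels follow the
scaffold, 5-fold k-NN models on ECFP0, ECFP4, the embedding, and an
ECFP4+embedding ensemble all reach Cohen's kappa > 0.88
(`knn_benchmark()`).

A thin command-line interface over the same functions is installed at
`inst/cli/moltriplet.R` (`standardize`, `keys`, `cluster`, `sample`,
`train`, `embed`, `fixtures-library`, `fixtures-activity`).

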