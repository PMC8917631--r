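# Shared fixtures, built once per test run and cached. The expensive objects
# (the full synthetic library, the dataset pipeline and the trained model)
# are shared across test files; everything is seeded and deterministic.

.fx <- new.env(parent = emptyenv())

# small library for fast structural tests
fixture_small_library <- function() {
  if (is.null(.fx$small_lib)) {
    .fx$small_lib <- generate_library(library_spec(n_per_scaffold = 40L))
  }
  .fx$small_lib
}

# full default library (the study conditions)
fixture_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- generate_library()
  .fx$lib
}

# small end-to-end dataset for fast training smoke tests
fixture_small_dataset <- function() {
  if (is.null(.fx$small_ds)) {
    .fx$small_ds <- build_triplet_dataset(
      fixture_small_library()$canonical_smiles,
      sampling_config(triplets_per_cluster = 5L))
  }
  .fx$small_ds
}

fixture_dataset <- function() {
  if (is.null(.fx$ds)) {
    .fx$ds <- build_triplet_dataset(fixture_library()$canonical_smiles,
                                    sampling_config(triplets_per_cluster = 12L))
  }
  .fx$ds
}

# held-out triplets never used for training (fresh seeded draw, exact
# training tuples removed)
fixture_eval_triplets <- function() {
  if (is.null(.fx$ev)) {
    ds <- fixture_dataset()
    ev <- sample_triplets(ds$clusters,
                          sampling_config(triplets_per_cluster = 3L,
                                          rng_seed = 271828L))
    key <- function(d) paste(d$anchor, d$positive, d$negative)
    .fx$ev <- ev[!(key(ev) %in% key(ds$triplets)), , drop = FALSE]
  }
  .fx$ev
}

# trained embedder at desk scale (shared by the metric-learning, deletion
# and benchmark checks)
fixture_model <- function() {
  if (is.null(.fx$model)) {
    ds <- fixture_dataset()
    fit <- train_embedder(
      ds$triplets,
      train_config(max_epochs = 60L, early_stopping_patience = 15L)
    )
    .fx$model <- fit$model
    .fx$train_log <- fit$log
  }
  .fx$model
}

.heavy_atom_counts_test <- function(lib) {
  moltriplet:::.heavy_atom_counts(lib$canonical_smiles)
}

# single-cluster cluster_set around the given member SMILES
.new_cs_for_test <- function(members, cluster_id = "GFRG:RG1\x1fGF1",
                             rg_key = "RG1") {
  moltriplet:::.new_cluster_set(data.frame(
    canonical_smiles = members, cluster_id = cluster_id,
    level = "GFRG", rg_key = rg_key, stringsAsFactors = FALSE
  ))
}

# alternative SMILES spellings of one molecule: permute the atom order of
# the parsed graph and write each permutation back through a (non-canonical)
# SMILES conversion
random_spellings <- function(smiles, k, seed = 1L) {
  set.seed(seed)
  mol <- parse_smiles(smiles)[[1]]
  n <- nrow(mol$atoms)
  out <- character(k)
  for (i in seq_len(k)) {
    perm <- sample.int(n)
    inv <- match(seq_len(n), perm)
    bonds <- data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                        order = mol$bonds$order)
    blk <- moltriplet:::.graph_to_molblock(mol$atoms$elem[perm], bonds, "x")
    smi <- suppressWarnings(ChemmineOB::convertFormat(
      "SDF", "SMI", blk,
      options = data.frame(names = "e", args = "")))
    out[i] <- sub("\t.*", "", strsplit(smi, "\n")[[1]][1])
  }
  out
}
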