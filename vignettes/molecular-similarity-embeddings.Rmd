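---
title: "Learning a molecular similarity metric from scaffold-based triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning a molecular similarity metric from scaffold-based triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Chemical similarity is usually computed as a Tanimoto coefficient over
hashed circular fingerprints (ECFP). That combination is strong in activity
benchmarks but has well-known failure modes: insensitivity to repeated
motifs (bit-set fingerprints saturate), over-reaction to changes that
perturb fragment hashing, and no meaningful behaviour on partial or
chemically invalid structures. `moltriplet` implements the alternative this
package is built around: a message-passing neural network (MPNN) trained
with the **triplet margin loss** so that Euclidean distance in a learned
16-dimensional embedding behaves as a molecular similarity metric.

Training data comes not from activity labels but from a *minimal structural
definition of similarity*. Every molecule gets three abstraction keys:

* **Reduced graph (RG)** - ring systems and acyclic atom groups collapse to
  typed nodes (aromatic ring / aliphatic ring / acyclic group, each with
  hydrogen-bond donor/acceptor flags); edges follow the bonds between
  groups.
* **Graph frame (GF)** - the Bemis-Murcko skeleton with side chains
  removed, every atom anonymized to carbon and every bond to a single bond.
* **Detailed frame (DF)** - the same skeleton keeping atom types and bond
  orders.

Molecules sharing RG and GF form **GFRG clusters** (DFRG clusters use DF
instead). A training example is a triplet *(anchor, positive, negative)*:
anchor and positive come from the same cluster; the negative shares only
the anchor's reduced graph, so it is "similar but less so" - deliberately a
hard negative rather than a random molecule, because chemical space grows
towards dissimilarity and easy negatives teach nothing.

The loss is `max(0, d(a,p) - d(a,n) + margin)` with Euclidean `d`. One
shared-parameter network embeds all three graphs of a triplet; Adam
minimizes the mean batch loss.

## Dataset construction rules

The pipeline (`build_triplet_dataset()`) applies, in order:

1. **Standardization** (`standardize_collection()`): parent structure =
   largest organic fragment with charges neutralized where a neutral form
   exists; discard reasons accumulate - parse failure, valence violations,
   wildcard atoms/bonds, isotope labels, elements outside
   {N, O, C, S, F, Cl, Br, I}, molecular weight above 650 Da, REOS reactive
   alerts, PAINS family-A alerts. Tautomer canonicalization is deliberately
   not applied. Deduplication on canonical SMILES keeps the first
   occurrence (a streaming-friendly, deterministic policy).
2. **Cluster size rules**: GFRG clusters with fewer than 4 members are
   dropped; GFRG clusters with 10,000 or more members are replaced by their
   DFRG sub-clusters; DFRG clusters above 20,000 members are randomly
   subsampled (seeded) to exactly 20,000.
3. **Centroids and identity filter**: the cluster centroid is the member
   with maximal mean ECFP4 Tanimoto similarity to the others (ties: fewer
   heavy atoms, then lexicographic). "Number of identities" is interpreted
   as the fraction of members whose ECFP4 fingerprint equals the
   centroid's (Tanimoto exactly 1); clusters with ratio strictly above 0.4
   are discarded. The alternative reading (pairwise identities across the
   whole cluster) is documented but not implemented.
4. **Reduced-graph prune**: only reduced graphs with at least two surviving
   clusters are kept (a negative must exist), iterated to a fixed point.
5. **Sampling**: per cluster, anchor/positive are an unordered random pair
   (then randomly assigned), the negative cluster is drawn uniformly among
   the other clusters of the same reduced graph, then a member uniformly.
   Everything is deterministic given `rng_seed` (default 42).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_gfrg_size` | 4 | minimum GFRG cluster size |
| `gfrg_to_dfrg_threshold` | 10,000 | switch to DFRG sub-clusters |
| `dfrg_cap` | 20,000 | DFRG subsampling cap |
| `identity_ratio_max` | 0.4 | identity-filter threshold (strict) |
| `triplets_per_cluster` | 10 | triplet draws per sampling cluster |
| `margin` | 1.0 | triplet loss margin (the loss implementation default; the protocol keeps hyperparameters unoptimized) |
| `batch_size` / `learning_rate` | 128 / 1e-3 | Adam protocol |
| `early_stopping_patience` | 25 epochs | on a seeded 10% validation split |
| `embedding_dim` | 16 | output size |
| node/edge ablation | 1% / 5% | per-graph regularization during training |

The network itself is three message-passing steps of width 48 over a
29-feature atom schema (element, degree, formal charge, a bond-order-derived
hybridization class, aromaticity, hydrogen count, ring membership) and a
5-feature bond schema (order, aromaticity, ring membership), with sum
pooling and a linear readout. Sum pooling plus neighbour-sum message
passing makes the embedding exactly permutation invariant, which the tests
assert to 1e-5 over 100 renumberings per molecule. A `max_epochs` cap
(default 500; desk runs use 60) is added so runs terminate without a GPU
budget; training keeps the best-validation parameters.

Node ablation removes the node *and its incident edges* (feature masking is
the alternative reading; removal is the documented choice), independently
for each of the three graphs of a triplet, training only. If every node of
a graph would drop, one uniformly chosen node is kept - an empty graph is
not a valid network input.

## The chemistry backend

All chemistry goes through OpenBabel (via `ChemmineOB` conversions and the
`obabel` executable for batch fingerprints and SMARTS screening):
canonical SMILES, molecular graphs (a small tolerant V2000 reader handles
single-atom molecules), charge neutralization, 4096-bit ECFP0/ECFP4
fingerprints, and explicit-hydrogen SMARTS matching - the published PAINS
family-A patterns use explicit `[#1]` atoms and only match with hydrogens
added. Aromaticity is read off the canonical SMILES token order, which
OpenBabel preserves when writing SDF; ring membership is computed as
"not a bridge" on the bond graph. The REOS alert list is a versioned,
editable text asset of classic reactivity alerts; the reduced-graph typing
scheme is likewise a versioned JSON asset (donors: N/O/S bearing hydrogen;
acceptors: N except aromatic N-H, and O; single-atom terminal substituents
merge into the adjacent ring node, which is what makes a phenol one
aromatic donor+acceptor node). Ionization-state and ring-size features are
deliberately not part of the node vocabulary, and the reduced graph is
insensitive to amide orientation by construction.

## The synthetic library (what it emulates, what it does not)

`generate_library()` enumerates 13 scaffold templates against a small
substituent set (H, F, Cl, Br, methyl, ethyl, propyl, methoxy,
hydroxymethyl; halogens are excluded on aliphatic ring carbons because they
would - correctly - trigger the reactive alkyl-halide alert). Templates
come in reduced-graph-sharing pairs that differ in ring size or ring
composition (benzene/thiophene, cyclohexane/cyclopentane/decalin,
phenol/hydroxythiophene, pyridine/oxazole, biphenyl/phenylthiophene,
cyclohexanol/cyclopentanol), which reproduces at small scale the cluster
geometry the sampler needs: several GFRG clusters under one reduced graph.
The default spec yields ~2,350 unique molecules and ~150 sampling
clusters; with 12 triplets per cluster that is ~1,840 training triplets,
which trains in a few minutes on one CPU.

What the fixture does *not* emulate: realistic drug-likeness or property
distributions, scaffold diversity at database scale, stereochemistry, or
clusters large enough to exercise the 10k/20k size rules on real data
(those rules are exercised with synthetic key tables instead). Passing
tests therefore demonstrate the machinery and its qualitative properties,
not performance on real screening collections.

`generate_activity()` builds per-target activity tables from scaffold
families: three inactive families at base pIC50 4.3/5.3/6.3 and one
heteroatom-marked active family at 8.3 (noise sd 0.15). The bases are
chosen so the 75th percentile falls in the gap below the active cloud and
the two-sided threshold rule accepts with margin; the active scaffold is
always compositionally distinct (N/S/O heterocycle) so that even radius-0
fingerprints can recover the signal, which is what makes the
ECFP0-kappa inclusion rule meaningful at this scale. Under the `random`
rule the same values are permuted across the target's structures, giving a
label set with identical marginal distribution and no structural signal.

## The activity threshold rule

The candidate threshold is the 75th percentile of a target's pIC50 values,
accepted only if it sits at least one sample standard deviation above the
minimum *and* below the maximum. The phrase this rule encodes is ambiguous;
the package implements the two-sided reading as default and exposes the
min-only reading as `rule = "min_only"`. Worked through, the two-sided rule
rejects a tight half/half bimodal mixture (t falls on the upper mode, so
max - s < t) and rejects uniform values (t too close to the maximum); it
accepts multi-level designs whose upper quartile is separated by a gap.
Constant inputs are always rejected.

## Statistics

Cohen's kappa, Cochran's Q (chi-squared approximation) and the exact
two-sided binomial McNemar test are implemented in closed form and verified
against brute-force references over *all* 8-sample x 3-classifier
correctness designs (up to row permutation, which leaves the statistics
unchanged - 6,435 distinct designs) and against `binom.test`. Pairwise
McNemar p-values are Bonferroni-corrected by 3. The k-NN classifier votes
over exactly k = 5 neighbours (`use.all = FALSE`): vote-over-all-ties would
turn the ECFP0 classifier into a de-facto majority-class predictor whenever
many molecules share identical radius-0 fingerprints, which distorts the
paired comparison. The ensemble averages the ECFP4 and embedding
classifiers' neighbour-vote probabilities and thresholds at 0.5.

## Numerical choices and degenerate inputs

* Distance ties in the ordering comparison count as failures for that
  metric and are logged separately (ties are common for Tanimoto, rare for
  float embeddings).
* Zero anchor-positive or anchor-negative distance in the loss gradient is
  guarded at 1e-12.
* `cohen_kappa` returns 0 when chance agreement is 1 (no-information case);
  Cochran's Q returns Q = 0, p = 1 when no sample shows disagreement.
* Deletion-probe draws that would empty a graph, or that select an edge
  already removed by a node deletion in the same draw, are redrawn and
  counted.
* Fingerprint bit positions use a fixed bijection from the backend's hex
  output; only consistency matters for Tanimoto values, and the test suite
  pins one backend-printed similarity value as an oracle.

## Known limitations, and two desk-scale facts

Two properties one might expect of the evaluation do not hold at desk
scale, and the package documents rather than hides them:

* **A randomly initialized MPNN is not a chance-level control.** Untrained
  models order 76-97% of held-out triplets correctly (measured across init
  seeds): random message-passing features already encode composition and
  size, and negatives differ from positives systematically by
  construction. A true chance control (random swap of positive/negative)
  measures 50.7%. The learned metric's contribution is the *margin
  structure* (trained accuracy 1.00, positive/negative distance
  distributions separated at p < 1e-100), not the mere ordering.
* **Null-benchmark kappas at 200 structures per target have sd ~ 0.07**, so
  individual permuted-label kappas regularly exceed 0.1 in magnitude even
  though their expectation is 0; a +-0.1 band on every kappa is calibrated
  for the 5,000-20,000-structure scale of the source benchmark setting,
  not for fixtures. Cochran's Q under the null is non-significant across
  seeds once k-NN votes over exactly k neighbours.

Other limitations: OpenBabel's ECFP implementation (4096 bits) stands in
for the more common 2048-bit variant; aromaticity and Kekulé conventions
follow OpenBabel; no tautomer handling; the reduced-graph scheme is one
defensible member of a family of published schemes and is shipped as a
replaceable asset.

## Reproducing the numbers

```{r, eval = FALSE}
library(moltriplet)
lib <- generate_library()
ds <- build_triplet_dataset(lib$canonical_smiles,
                            sampling_config(triplets_per_cluster = 12))
fit <- train_embedder(ds$triplets,
                      train_config(max_epochs = 60,
                                   early_stopping_patience = 15))
ev <- sample_triplets(ds$clusters,
                      sampling_config(triplets_per_cluster = 3,
                                      rng_seed = 271828))
compare_orderings(fit$model, ev)$summary
```

`scripts/acceptance.R` runs exactly this end to end (library, pipeline,
training, ordering, distance distributions, deletion probe, signal and
null benchmarks) from a single `--seed` and writes the computed quantities
as JSON. The problem sizes - ~2,350 molecules, ~1,840 training triplets,
60-epoch cap, 20 probe molecules, 3 activity targets of 200 structures -
are the package's desk-scale defaults.
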