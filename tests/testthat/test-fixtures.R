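# Synthetic library and activity generators: determinism, standardization
# round trip, cluster-structure guarantees, label rules.

test_that("library generation is deterministic and standardize-stable", {
  spec <- library_spec(n_per_scaffold = 30L)
  lib1 <- generate_library(spec)
  lib2 <- generate_library(spec)
  expect_identical(lib1, lib2)
  expect_false(any(duplicated(lib1$canonical_smiles)))
  expect_identical(lib1$canonical_smiles, sort(lib1$canonical_smiles))
  # round trip: every molecule passes standardization unchanged
  std <- standardize_collection(lib1$canonical_smiles[1:50])
  expect_true(all(std$verdict == "KEEP"))
  expect_identical(std$canonical_smiles, lib1$canonical_smiles[1:50])
})

test_that("the library carries multi-cluster reduced-graph structure", {
  lib <- fixture_small_library()
  ks <- key_set(lib$canonical_smiles)
  per_rg <- tapply(paste(ks$rg_key, ks$gf_key), ks$rg_key,
                   function(x) length(unique(x)))
  expect_gt(sum(per_rg >= 2), 0)
  # ring-size pairs: 5- and 6-membered carbocycle frames both present
  expect_true(all(c("C1CCCC1", "C1CCCCC1") %in% ks$gf_key))
})

test_that("scaffold-paired templates share reduced graphs across ring sizes", {
  ks <- key_set(canonical_smiles(c("c1ccccc1", "c1ccsc1",
                                   "C1CCCCC1", "C1CCCC1")))
  expect_equal(ks$rg_key[1], ks$rg_key[2]) # benzene ~ thiophene
  expect_equal(ks$rg_key[3], ks$rg_key[4]) # cyclohexane ~ cyclopentane
  expect_false(ks$gf_key[1] == ks$gf_key[2])
  expect_false(ks$gf_key[3] == ks$gf_key[4])
})

test_that("activity tables honour counts, ranges and label rules", {
  lib <- fixture_library()
  spec <- activity_spec(n_targets = 2L, structures_per_target = 60L)
  act <- generate_activity(spec, lib)
  expect_equal(nrow(act), 120)
  expect_equal(as.integer(table(act$target_id)), c(60L, 60L))
  expect_true(all(act$pic50 >= 3 & act$pic50 <= 11))
  # determinism
  expect_identical(act, generate_activity(spec, lib))
  # scaffold-determined: scaffold explains almost all variance
  fit <- stats::aov(pic50 ~ scaffold, data = act)
  expect_gt(summary(fit)[[1]]$`F value`[1], 100)
  # random rule: same value multiset per target, no scaffold signal
  actr <- generate_activity(activity_spec(n_targets = 2L,
                                          structures_per_target = 60L,
                                          label_rule = "random"), lib)
  for (tg in unique(act$target_id)) {
    a <- sort(act$pic50[act$target_id == tg])
    b <- sort(actr$pic50[actr$target_id == tg])
    expect_equal(a, b, tolerance = 1e-12)
  }
  fitr <- stats::aov(pic50 ~ scaffold, data = actr)
  expect_lt(summary(fitr)[[1]]$`F value`[1], 5)
})

test_that("an unsatisfiable library spec fails at generation time", {
  # benzene-only templates cannot give two frame clusters under one
  # reduced graph (all members share the 6-ring frame and a featureless
  # aromatic node)
  spec <- library_spec(
    scaffolds = data.frame(name = c("benzene", "toluene"),
                           template = c("c1cc(*)ccc1", "Cc1cc(*)ccc1"),
                           allow_halogens = c(TRUE, TRUE)),
    substituents = c("", "C"), n_per_scaffold = 10L)
  expect_error(generate_library(spec), "two-cluster")
})
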