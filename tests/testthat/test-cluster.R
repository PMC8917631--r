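# Cluster construction rules, centroid/identity computations and triplet
# sampling, mostly on synthetic key tables (no chemistry needed for the
# size-rule logic).

# helper: a key table of n molecules sharing one rg/gf/df combination
synth_keys <- function(n, rg = "RG1", gf = "GF1", df = "DF1", prefix = "m") {
  data.frame(
    canonical_smiles = sprintf("%s%d", prefix, seq_len(n)),
    rg_key = rep(rg, n), gf_key = rep(gf, n), df_key = rep(df, n),
    stringsAsFactors = FALSE
  )
}

test_that("GFRG size rules drop small and split large clusters", {
  cfg <- sampling_config()
  # 3 members: dropped; 4 members: kept
  cs3 <- build_clusters(synth_keys(3), cfg)
  expect_equal(nrow(cs3$clusters), 0)
  expect_equal(cs3$log$n_dropped_small, 3L)
  cs4 <- build_clusters(synth_keys(4), cfg)
  expect_equal(nrow(cs4$clusters), 1)
  expect_equal(cs4$clusters$size, 4L)
  expect_equal(cs4$clusters$level, "GFRG")

  # 12,000-member GFRG cluster splits into its DFRG sub-clusters
  big <- rbind(synth_keys(8000, df = "DFa", prefix = "a"),
               synth_keys(4000, df = "DFb", prefix = "b"))
  csb <- build_clusters(big, cfg)
  expect_equal(nrow(csb$clusters), 2)
  expect_true(all(csb$clusters$level == "DFRG"))
  expect_equal(sort(csb$clusters$size), c(4000L, 8000L))
})

test_that("oversized DFRG clusters subsample to exactly the cap", {
  cfg <- sampling_config()
  keys <- synth_keys(25000)
  cs <- build_clusters(keys, cfg)
  expect_equal(cs$clusters$level, "DFRG")
  expect_equal(cs$clusters$size, 20000L)
  expect_equal(nrow(cs$members), 20000L)
  # deterministic given the seed
  cs2 <- build_clusters(keys, cfg)
  expect_identical(cs$members, cs2$members)
  # conservation: kept + subsampled-away = input
  expect_equal(nrow(cs$members) + cs$log$n_subsampled_away, nrow(keys))
  expect_equal(build_clusters(synth_keys(0), cfg)$log$n_input, 0L)
})

test_that("centroid maximizes mean similarity with heavy-atom tie-break", {
  mem <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccc2ccccc2c1")
  cs <- .new_cs_for_test(mem)
  cs <- assign_centroids(cs)
  # brute-force oracle: exhaustive pairwise Tanimoto matrix
  fp <- ecfp_fingerprints(mem, "ECFP4")
  sim <- tanimoto_similarity(fp)
  mean_sim <- (rowSums(sim) - 1) / (length(mem) - 1)
  expect_equal(cs$clusters$centroid, mem[which.max(mean_sim)])

  # singleton cluster: its only member, identity ratio 1
  cs1 <- assign_centroids(.new_cs_for_test("CCO"))
  expect_equal(cs1$clusters$centroid, "CCO")
  expect_equal(cs1$clusters$identity_ratio, 1)

  # duplicated members share the centroid fingerprint: ratio counts them
  csd <- assign_centroids(.new_cs_for_test(c("CCO", "CCO", "CCCCO", "CCCO")))
  expect_equal(csd$clusters$identity_ratio, 0.5)
})

test_that("identity filter discards strictly above the threshold", {
  cfg <- sampling_config()
  cs <- .new_cs_for_test(paste0("m", 1:10))
  cs$clusters$identity_ratio <- 0.5
  cs$clusters$centroid <- "m1"
  expect_equal(nrow(identity_filter(cs, cfg)$clusters), 0)
  cs$clusters$identity_ratio <- 0.4 # exactly at the threshold: kept
  expect_equal(nrow(identity_filter(cs, cfg)$clusters), 1)
})

test_that("reduced graphs with a single cluster are pruned to a fixed point", {
  mk <- function(n, rg, gf, prefix) synth_keys(n, rg = rg, gf = gf,
                                               prefix = prefix)
  keys <- rbind(mk(5, "RG1", "GFa", "a"), mk(5, "RG1", "GFb", "b"),
                mk(5, "RG2", "GFc", "c"))
  cs <- build_clusters(keys, sampling_config())
  pr <- prune_single_cluster_rgs(cs)
  expect_equal(sort(unique(pr$clusters$rg_key)), "RG1")
  expect_equal(nrow(pr$clusters), 2)
  expect_equal(pr$log$n_rg_prune_dropped_members, 5L)
})

test_that("triplet sampling respects cluster and reduced-graph membership", {
  keys <- rbind(synth_keys(5, gf = "GFa", prefix = "a"),
                synth_keys(5, gf = "GFb", prefix = "b"))
  cs <- build_clusters(keys, sampling_config(triplets_per_cluster = 50L))
  tr <- sample_triplets(cs, sampling_config(triplets_per_cluster = 50L))
  expect_equal(nrow(tr), 100)
  a_clu <- substr(tr$anchor, 1, 1)
  p_clu <- substr(tr$positive, 1, 1)
  n_clu <- substr(tr$negative, 1, 1)
  expect_true(all(a_clu == p_clu))
  expect_true(all(a_clu != n_clu))
  expect_true(all(tr$anchor != tr$positive))
  expect_true(all(tr$rg_key == "RG1"))
  # seeded determinism
  tr2 <- sample_triplets(cs, sampling_config(triplets_per_cluster = 50L))
  expect_identical(tr, tr2)
})

test_that("train/test split is a deterministic exhaustive partition", {
  tr <- data.frame(anchor = paste0("a", 1:1000), positive = "p",
                   negative = "n", stringsAsFactors = FALSE)
  sp <- train_test_split(tr, 0.1, rng_seed = 42L)
  expect_equal(nrow(sp$train), 100)
  expect_equal(nrow(sp$test), 900)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(tr)))
  sp2 <- train_test_split(tr, 0.1, rng_seed = 42L)
  expect_identical(sp, sp2)
  tiny <- train_test_split(tr[1:2, ], 0.5)
  expect_equal(nrow(tiny$train), 1)
  expect_equal(nrow(tiny$test), 1)
})
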