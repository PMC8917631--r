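# Reduced graphs, Bemis-Murcko frames and cluster key sets.

test_that("reduced graph nodes carry ring class and donor/acceptor typing", {
  ph <- reduced_graph("Oc1ccccc1")
  expect_equal(nrow(ph$nodes), 1)
  expect_equal(ph$nodes$ring_class, "Ar")
  expect_true(ph$nodes$donor && ph$nodes$acceptor)

  ch <- reduced_graph("C1CCCCC1")
  expect_equal(ch$nodes$label, "Al")

  chol <- reduced_graph("OC1CCCCC1")
  expect_equal(nrow(chol$nodes), 1)
  expect_equal(chol$nodes$ring_class, "Al")
  expect_true(chol$nodes$donor)

  bi <- reduced_graph("c1ccc(-c2ccccc2)cc1")
  expect_equal(nrow(bi$nodes), 2)
  expect_equal(nrow(bi$edges), 1)
  expect_equal(bi$nodes$label, c("Ar", "Ar"))
})

test_that("the scheme distinguishes S-H donors from hydroxyl groups", {
  ol <- key_set(c("OC1CCCCC1", "SC1CCCCC1"))
  expect_identical(ol$gf_key[1], ol$gf_key[2])
  expect_false(ol$rg_key[1] == ol$rg_key[2])
})

test_that("murcko frames prune side chains and anonymize", {
  tol <- murcko_frames("Cc1ccccc1")
  expect_equal(tol$detailed_frame, "c1ccccc1")
  expect_equal(tol$graph_frame, "C1CCCCC1")
  but <- murcko_frames("CCCC")
  expect_true(but$is_acyclic)
  expect_equal(but$detailed_frame, "")
  expect_equal(but$graph_frame, "")
  # ring size is preserved in the graph frame
  f5 <- murcko_frames("C1CCCC1")
  f6 <- murcko_frames("C1CCCCC1")
  expect_false(f5$graph_frame == f6$graph_frame)
})

test_that("keys are invariant under atom renumbering", {
  mols <- c("Oc1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
            "c1ccc(-c2ccsc2)cc1", "OC1CCC(CC1)C1CCCC1")
  for (s in mols) {
    can <- canonical_smiles(s)
    sp <- unique(c(can, canonical_smiles(random_spellings(can, 15))))
    expect_identical(sp, can) # canonicalization collapses spellings
    keys <- key_set(rep(can, 1))
    resp <- random_spellings(can, 15, seed = 7)
    keys2 <- key_set(canonical_smiles(resp))
    expect_true(all(keys2$rg_key == keys$rg_key))
    expect_true(all(keys2$gf_key == keys$gf_key))
    expect_true(all(keys2$df_key == keys$df_key))
  }
})

test_that("detailed frame determines graph frame (abstraction hierarchy)", {
  lib <- fixture_small_library()
  ks <- key_set(lib$canonical_smiles[seq_len(min(200, nrow(lib)))])
  per_df <- tapply(ks$gf_key, ks$df_key, function(x) length(unique(x)))
  expect_true(all(per_df == 1))
  # anonymizing the detailed frame reproduces the graph frame
  cyc <- ks[nzchar(ks$df_key), ][1:10, ]
  re <- vapply(cyc$df_key, function(d) murcko_frames(d)$graph_frame,
               character(1), USE.NAMES = FALSE)
  expect_equal(re, cyc$gf_key)
})

test_that("key computation is deterministic and node count is bounded", {
  lib <- fixture_small_library()
  sm <- lib$canonical_smiles[1:50]
  k1 <- key_set(sm)
  k2 <- key_set(sm)
  expect_identical(k1, k2)
  for (s in sm[1:10]) {
    rg <- reduced_graph(s)
    expect_lte(nrow(rg$nodes), nrow(parse_smiles(s)[[1]]$atoms))
    g <- igraph::graph_from_edgelist(
      if (nrow(rg$edges)) rg$edges else matrix(integer(0), 0, 2),
      directed = FALSE)
    if (igraph::vcount(g) < nrow(rg$nodes)) {
      g <- igraph::add_vertices(g, nrow(rg$nodes) - igraph::vcount(g))
    }
    expect_true(igraph::is_connected(g) || nrow(rg$nodes) == 1)
  }
})
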