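# Featurization, ablation, the embedding network and triplet-loss training.

test_that("featurization reflects molecular topology", {
  g <- featurize(c("C", "CC", "c1ccccc1"))
  expect_equal(g[[1]]$n, 1)
  expect_equal(nrow(g[[1]]$edges), 0)
  expect_equal(g[[2]]$n, 2)
  expect_equal(nrow(g[[2]]$edges), 1)
  expect_equal(g[[3]]$n, 6)
  expect_equal(nrow(g[[3]]$edges), 6)
  # aromatic flag column: after element(9)+degree(6)+charge(3)+hybrid(4)
  expect_equal(sum(g[[3]]$node_x[, 23]), 6)
  expect_error(featurize("xyz"), "unparseable")
})

test_that("ablation honours probabilities and the keep-one-node floor", {
  g <- featurize("c1ccccc1CCCCO")[[1]]
  set.seed(1)
  expect_identical(ablate(g, 0, 0), g)
  gb <- ablate(g, 1, 0)
  expect_equal(gb$n, 1)
  # Monte-Carlo drop rates on a 100-node ring (100 edges)
  ring <- list(n = 100L,
               node_x = matrix(0, 100, moltriplet:::.node_feature_dim()),
               edges = cbind(1:100, c(2:100, 1)),
               edge_x = matrix(0, 100, moltriplet:::.edge_feature_dim()),
               smiles = "ring")
  class(ring) <- "mol_graph"
  set.seed(42)
  trials <- 10000
  node_drop <- edge_drop <- numeric(trials)
  for (i in seq_len(trials)) {
    a <- ablate(ring, 0.01, 0.05)
    node_drop[i] <- (100 - a$n) / 100
    edge_drop[i] <- nrow(a$edges)
  }
  expect_lt(abs(mean(node_drop) - 0.01), 3 * sqrt(0.01 * 0.99 / (100 * trials)))
  # edges survive if both endpoints kept (p = 0.99^2) and then with p = 0.95
  exp_edges <- 100 * 0.99^2 * 0.95
  expect_lt(abs(mean(edge_drop) - exp_edges) / 100,
            3 * sqrt(0.95 * 0.05 / (100 * trials)) + 0.01)
})

test_that("triplet margin loss matches an independent scalar oracle", {
  # hand-coded scalar reference, independent of the vectorized path
  scalar_loss <- function(a, p, n, margin) {
    dap <- sqrt(sum((a - p)^2))
    dan <- sqrt(sum((a - n)^2))
    max(0, dap - dan + margin)
  }
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    d <- sample(2:16, 1)
    a <- rnorm(d); p <- rnorm(d); n <- rnorm(d)
    m <- runif(1, 0.1, 2)
    worst <- max(worst, abs(triplet_margin_loss(a, p, n, m) -
                              scalar_loss(a, p, n, m)))
  }
  expect_lt(worst, 1e-6)
  # boundary cases
  expect_equal(triplet_margin_loss(c(0, 0), c(1, 0), c(3, 0), 1), 0)
  expect_equal(triplet_margin_loss(c(0, 0), c(2, 0), c(0, 2), 1), 1)
  expect_equal(triplet_margin_loss(c(1, 1), c(1, 1), c(3, 1), 1), 0)
  expect_error(triplet_margin_loss(c(0, 0), c(1, 0, 0), c(1, 0), 1),
               "mismatch")
})

test_that("embedding is deterministic, 16-dimensional and order-invariant", {
  model <- mpnn_init()
  sm <- canonical_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  z1 <- embed_graphs(model, sm)
  z2 <- embed_graphs(model, sm)
  expect_identical(z1, z2)
  expect_equal(ncol(z1), 16)
  expect_true(all(is.finite(z1)))
  sp <- random_spellings(sm, 25, seed = 3)
  zs <- embed_graphs(model, canonical_smiles(sp))
  expect_lt(max(abs(sweep(zs, 2, z1[1, ]))), 1e-10)
})

test_that("training is seeded-reproducible and reduces validation loss", {
  ds <- fixture_small_dataset()
  trip <- ds$triplets[seq_len(min(200, nrow(ds$triplets))), ]
  cfg <- train_config(max_epochs = 5L, batch_size = 64L)
  f1 <- train_embedder(trip, cfg)
  f2 <- train_embedder(trip, cfg)
  expect_identical(f1$log$val_loss, f2$log$val_loss)
  expect_lt(min(f1$log$val_loss), f1$log$val_loss[1] + 1e-9)
  # the best-validation parameters are the ones returned
  expect_equal(attr(f1$log, "config")$best_epoch,
               f1$log$epoch[which.min(f1$log$val_loss)])
  expect_error(train_embedder(trip[0, ], cfg), "empty")
})

test_that("ablated (chemically invalid) graphs embed and train without error", {
  model <- mpnn_init()
  g <- featurize(c("c1ccccc1CCN", "OC1CCCC1"))
  set.seed(5)
  broken <- lapply(rep(g, 5), ablate, node_drop_prob = 0.4,
                   edge_drop_prob = 0.4)
  z <- embed_graphs(model, broken)
  expect_true(all(is.finite(z)))
  # a full training step on heavily ablated graphs still yields finite loss
  trip <- data.frame(anchor = "c1ccccc1CCN", positive = "c1ccccc1CCO",
                     negative = "OC1CCCC1")
  trip <- trip[rep(1, 8), ]
  fit <- train_embedder(trip, train_config(max_epochs = 1L, batch_size = 4L),
                        ablation_config(0.3, 0.3))
  expect_true(all(is.finite(fit$log$train_loss)))
})

test_that("models survive a save/load round trip", {
  model <- mpnn_init(rng_seed = 11L)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  sm <- c("CCO", "c1ccccc1")
  expect_equal(embed_graphs(back, sm), embed_graphs(model, sm),
               tolerance = 1e-12)
  expect_equal(back$config$embedding_dim, 16)
})
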