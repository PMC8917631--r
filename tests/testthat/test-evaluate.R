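# Evaluation probes: ordering comparison, distance distributions, deletion
# probe bookkeeping, the activity threshold rule, and the statistical
# machinery (kappa, Cochran's Q, exact McNemar) against independent oracles.

test_that("ordering summary partitions the triplets and flags match distances", {
  ds <- fixture_small_dataset()
  trip <- ds$triplets[seq_len(min(150, nrow(ds$triplets))), ]
  model <- mpnn_init()
  out <- compare_orderings(model, trip)
  s <- out$summary
  expect_equal(s$n_both_correct + s$n_fp_only_fail + s$n_emb_only_fail +
                 s$n_both_fail, s$n)
  expect_equal(s$n, nrow(trip))
  r <- out$records
  expect_true(all(r$emb_correct == (r$d_emb_pos < r$d_emb_neg)))
  expect_true(all(r$fp_correct == (r$d_fp_pos < r$d_fp_neg)))
  expect_true(all(r$d_fp_pos >= 0 & r$d_fp_pos <= 1))
  expect_true(all(r$d_emb_pos >= 0))
})

test_that("identical positive and negative inputs give identical distributions", {
  trip <- data.frame(anchor = c("CCO", "c1ccccc1"),
                     positive = c("CCCO", "Cc1ccccc1"),
                     negative = c("CCCO", "Cc1ccccc1"))
  dd <- distance_distributions(mpnn_init(), trip)
  expect_identical(dd$positive, dd$negative)
  expect_equal(dd$summary$mean_diff, 0)
})

test_that("activity threshold implements the two-sided margin rule", {
  # constant input: rejected
  expect_false(activity_threshold(c(4, 4, 4, 4))$accepted)
  # uniform on [4, 9]: the 75th percentile sits too close to the maximum
  set.seed(1)
  u <- runif(1000, 4, 9)
  ru <- activity_threshold(u)
  expect_false(ru$accepted)
  expect_equal(ru$stats$t, 7.73, tolerance = 0.01)
  expect_equal(ru$stats$s, 1.44, tolerance = 0.01)
  # tight bimodal: two-sided rejects, min-only accepts
  set.seed(2)
  bim <- c(rnorm(500, 5, 0.1), rnorm(500, 8.5, 0.1))
  expect_false(activity_threshold(bim)$accepted)
  expect_true(activity_threshold(bim, rule = "min_only")$accepted)
  # well-separated four-level design: accepted, threshold in the gap
  set.seed(3)
  mix <- c(rnorm(150, 4.3, .15), rnorm(150, 5.3, .15),
           rnorm(150, 6.3, .15), rnorm(150, 8.3, .15))
  rm <- activity_threshold(mix)
  expect_true(rm$accepted)
  expect_gt(rm$threshold, 6.8)
  expect_lt(rm$threshold, 7.9)
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohen_kappa(matrix(c(40, 5, 10, 45), 2, 2)), 0.7)
  expect_equal(cohen_kappa(matrix(c(30, 0, 0, 20), 2, 2)), 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2, 2)), 0)
  # degenerate chance agreement of 1: defined as 0
  expect_equal(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), 0)
  # vector interface agrees with the table interface
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  truth <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(cohen_kappa(pred, truth),
               cohen_kappa(table(factor(pred, c(FALSE, TRUE)),
                                 factor(truth, c(FALSE, TRUE)))))
})

test_that("Cochran's Q agrees with a brute-force reference on all 8-sample designs", {
  # literal-formula reference, coded independently of the implementation
  q_ref <- function(x) {
    k <- ncol(x); n <- nrow(x)
    G <- numeric(k); L <- numeric(n)
    for (j in 1:k) for (i in 1:n) G[j] <- G[j] + x[i, j]
    for (i in 1:n) L[i] <- sum(x[i, ])
    num <- 0
    for (j in 1:k) num <- num + (G[j] - mean(G))^2
    den <- k * sum(L) - sum(L^2)
    if (den <= 0) return(list(Q = 0, p = 1))
    Q <- k * (k - 1) * num / den
    list(Q = Q, p = pchisq(Q, k - 1, lower.tail = FALSE))
  }
  # every 8 x 3 correctness matrix is, up to row permutation (which leaves Q
  # unchanged), a multiset of 8 row patterns from the 2^3 possibilities:
  # enumerate all multisets
  patterns <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  combos <- utils::combn(8 + 8 - 1, 8 - 1) # stars and bars over 8 patterns
  n_checked <- 0L
  for (ci in seq_len(ncol(combos))) {
    bars <- c(0, combos[, ci], 16)
    counts <- diff(bars) - 1
    x <- patterns[rep(1:8, counts), , drop = FALSE]
    got <- cochran_q(x)
    ref <- q_ref(x)
    expect_equal(got$Q, ref$Q, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, choose(15, 7))
})

test_that("exact McNemar agrees with the exact binomial reference", {
  # all discordant splits reachable from 8 samples
  for (b in 0:8) for (cc in 0:(8 - b)) {
    got <- mcnemar_exact(b, cc)$p
    ref <- if (b + cc == 0) 1 else binom.test(min(b, cc), b + cc, 0.5)$p.value
    # the b == c case: two-sided doubling caps at 1
    if (b == cc && b + cc > 0) ref <- 1
    expect_equal(got, ref, tolerance = 1e-12)
  }
  expect_equal(mcnemar_exact(10, 0)$p, 2 * 0.5^10)
  # vector interface
  x <- c(TRUE, TRUE, FALSE, TRUE)
  y <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(mcnemar_exact(x, y)$b, 2)
  expect_equal(mcnemar_exact(x, y)$c, 0)
})

test_that("deletion probe is zero at zero deletions and non-negative", {
  model <- mpnn_init()
  sm <- c("c1ccccc1CCCN", "OC1CCCCC1CC", "Cc1ccc(CCO)cc1")
  dp <- deletion_probe(model, sm, max_deletions = 4L, trials_per_level = 3L)
  z0 <- dp$records$distance[dp$records$n_deleted == 0]
  expect_true(all(z0 == 0))
  expect_true(all(dp$records$distance >= 0))
  expect_equal(nrow(dp$per_level), 5)
  expect_error(deletion_probe(model, "CC", max_deletions = 4L), "elements")
})

test_that("knn benchmark excludes targets outside the structure window", {
  ds <- fixture_small_dataset()
  act <- data.frame(smiles = ds$standardized$kept$canonical_smiles[1:30],
                    target_id = "T1",
                    pic50 = rnorm(30, 6))
  bm <- knn_benchmark(act, mpnn_init()) # paper-scale window: 5k-20k
  expect_false(bm$T1$included)
  expect_equal(bm$T1$exclusion_reason, "structure_count")
})
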