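# Cluster construction and triplet sampling. Molecules sharing reduced-graph
# + graph-frame keys form GFRG clusters; oversized GFRG clusters are
# replaced by their DFRG (reduced-graph + detailed-frame) sub-clusters;
# clusters then pass centroid-based identity filtering and a reduced-graph
# multi-cluster requirement before anchor/positive/negative sampling.

#' Sampling configuration
#'
#' @param min_gfrg_size GFRG clusters smaller than this are removed.
#' @param gfrg_to_dfrg_threshold GFRG clusters at least this large are
#'   replaced by their DFRG sub-clusters.
#' @param dfrg_cap maximum DFRG cluster size; larger clusters are randomly
#'   subsampled to exactly this size.
#' @param identity_ratio_max clusters whose fraction of centroid-identical
#'   members (ECFP4 Tanimoto exactly 1) exceeds this are discarded.
#' @param triplets_per_cluster triplets emitted per sampling cluster.
#' @param rng_seed seed for subsampling and triplet draws.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(min_gfrg_size = 4L,
                            gfrg_to_dfrg_threshold = 10000L,
                            dfrg_cap = 20000L,
                            identity_ratio_max = 0.4,
                            triplets_per_cluster = 10L,
                            rng_seed = 42L) {
  stopifnot(min_gfrg_size > 0, gfrg_to_dfrg_threshold > 0, dfrg_cap > 0,
            identity_ratio_max > 0, identity_ratio_max <= 1,
            triplets_per_cluster > 0)
  structure(list(
    min_gfrg_size = as.integer(min_gfrg_size),
    gfrg_to_dfrg_threshold = as.integer(gfrg_to_dfrg_threshold),
    dfrg_cap = as.integer(dfrg_cap),
    identity_ratio_max = identity_ratio_max,
    triplets_per_cluster = as.integer(triplets_per_cluster),
    rng_seed = as.integer(rng_seed)
  ), class = "sampling_config")
}

.new_cluster_set <- function(members, log = list()) {
  cl <- unique(members[, c("cluster_id", "level", "rg_key")])
  sizes <- table(members$cluster_id)
  cl$size <- as.integer(sizes[cl$cluster_id])
  cl$centroid <- rep(NA_character_, nrow(cl))
  cl$identity_ratio <- rep(NA_real_, nrow(cl))
  rownames(cl) <- NULL
  rownames(members) <- NULL
  structure(list(members = members, clusters = cl, log = log),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$clusters), "clusters,",
      nrow(x$members), "members\n")
  if (nrow(x$clusters) > 0) print(table(x$clusters$level))
  invisible(x)
}

#' Build sampling clusters from key sets
#'
#' Applies the cluster size rules: GFRG clusters below `min_gfrg_size` are
#' dropped; GFRG clusters at or above `gfrg_to_dfrg_threshold` are replaced
#' by their DFRG sub-clusters; DFRG clusters above `dfrg_cap` are randomly
#' subsampled (seeded) to exactly `dfrg_cap` members.
#'
#' @param keys data.frame from [key_set()] (columns `canonical_smiles`,
#'   `rg_key`, `gf_key`, `df_key`).
#' @param config a [sampling_config()].
#' @return a `cluster_set`.
#' @export
build_clusters <- function(keys, config = sampling_config()) {
  if (nrow(keys) == 0) {
    m <- data.frame(canonical_smiles = character(0), cluster_id = character(0),
                    level = character(0), rg_key = character(0))
    return(.new_cluster_set(m, log = list(n_input = 0L, n_dropped_small = 0L)))
  }
  keys <- keys[order(keys$canonical_smiles), , drop = FALSE]
  gfrg <- paste0("GFRG:", keys$rg_key, "\x1f", keys$gf_key)
  sizes <- table(gfrg)
  small <- names(sizes)[sizes < config$min_gfrg_size]
  big <- names(sizes)[sizes >= config$gfrg_to_dfrg_threshold]
  keep <- !(gfrg %in% small)
  n_dropped_small <- sum(!keep)
  k2 <- keys[keep, , drop = FALSE]
  g2 <- gfrg[keep]
  use_dfrg <- g2 %in% big
  cluster_id <- ifelse(use_dfrg,
                       paste0("DFRG:", k2$rg_key, "\x1f", k2$df_key),
                       g2)
  members <- data.frame(
    canonical_smiles = k2$canonical_smiles,
    cluster_id = cluster_id,
    level = ifelse(use_dfrg, "DFRG", "GFRG"),
    rg_key = k2$rg_key,
    stringsAsFactors = FALSE
  )
  # cap DFRG clusters by seeded subsampling, deterministic processing order
  n_subsampled <- 0L
  dsizes <- table(members$cluster_id[members$level == "DFRG"])
  over <- sort(names(dsizes)[dsizes > config$dfrg_cap])
  if (length(over) > 0) {
    withr_seed <- config$rng_seed
    set.seed(withr_seed)
    drop_rows <- integer(0)
    for (cid in over) {
      rows <- which(members$cluster_id == cid)
      excess <- length(rows) - config$dfrg_cap
      drop_rows <- c(drop_rows, sample(rows, excess))
      n_subsampled <- n_subsampled + excess
    }
    members <- members[-drop_rows, , drop = FALSE]
  }
  .new_cluster_set(members, log = list(
    n_input = nrow(keys),
    n_dropped_small = n_dropped_small,
    n_subsampled_away = n_subsampled
  ))
}

.heavy_atom_counts <- function(smiles) {
  vapply(smiles, function(s) nrow(.smiles_atom_tokens(s)), integer(1),
         USE.NAMES = FALSE)
}

#' Assign ECFP4 centroids and identity ratios to clusters
#'
#' The centroid is the member maximizing mean ECFP4 Tanimoto similarity to
#' all other members; ties are broken by smaller heavy-atom count, then
#' lexicographically. The identity ratio is the fraction of members whose
#' ECFP4 fingerprint is identical (Tanimoto exactly 1) to the centroid's.
#'
#' @param cset a `cluster_set`.
#' @return the `cluster_set` with `centroid` and `identity_ratio` filled in.
#' @export
assign_centroids <- function(cset) {
  mem <- cset$members
  if (nrow(mem) == 0) return(cset)
  fps <- ecfp_fingerprints(mem$canonical_smiles, "ECFP4")
  hac <- .heavy_atom_counts(mem$canonical_smiles)
  for (ci in seq_len(nrow(cset$clusters))) {
    cid <- cset$clusters$cluster_id[ci]
    rows <- which(mem$cluster_id == cid)
    if (length(rows) == 1) {
      cset$clusters$centroid[ci] <- mem$canonical_smiles[rows]
      cset$clusters$identity_ratio[ci] <- 1
      next
    }
    sim <- tanimoto_similarity(fps[rows, , drop = FALSE])
    mean_sim <- (rowSums(sim) - 1) / (length(rows) - 1)
    ord <- order(-mean_sim, hac[rows], mem$canonical_smiles[rows])
    best <- rows[ord[1]]
    cset$clusters$centroid[ci] <- mem$canonical_smiles[best]
    ident <- sim[ord[1], ] >= 1 - 1e-12
    cset$clusters$identity_ratio[ci] <- sum(ident) / length(rows)
  }
  cset
}

#' Discard clusters with too many centroid-identical members
#'
#' A cluster is discarded iff its identity ratio strictly exceeds
#' `identity_ratio_max` (a ratio exactly at the threshold is kept).
#'
#' @param cset a `cluster_set` with centroids assigned.
#' @param config a [sampling_config()].
#' @return filtered `cluster_set`.
#' @export
identity_filter <- function(cset, config = sampling_config()) {
  stopifnot(!any(is.na(cset$clusters$identity_ratio)))
  drop <- cset$clusters$cluster_id[
    cset$clusters$identity_ratio > config$identity_ratio_max]
  keep_members <- cset$members[!(cset$members$cluster_id %in% drop), ,
                               drop = FALSE]
  out <- .new_cluster_set(keep_members, log = c(cset$log, list(
    n_identity_dropped_clusters = length(drop),
    n_identity_dropped_members = sum(cset$members$cluster_id %in% drop)
  )))
  # carry over centroid annotations for surviving clusters
  m <- match(out$clusters$cluster_id, cset$clusters$cluster_id)
  out$clusters$centroid <- cset$clusters$centroid[m]
  out$clusters$identity_ratio <- cset$clusters$identity_ratio[m]
  out
}

#' Keep only reduced graphs with at least two clusters
#'
#' Negative sampling needs a second cluster under the same reduced graph;
#' clusters whose reduced-graph key maps to a single surviving cluster are
#' removed. The prune iterates to a fixed point.
#'
#' @param cset a `cluster_set`.
#' @return pruned `cluster_set`.
#' @export
prune_single_cluster_rgs <- function(cset) {
  dropped_members <- 0L
  repeat {
    counts <- table(cset$clusters$rg_key)
    lone <- names(counts)[counts < 2]
    if (length(lone) == 0) break
    drop <- cset$clusters$rg_key %in% lone
    drop_ids <- cset$clusters$cluster_id[drop]
    dropped_members <- dropped_members +
      sum(cset$members$cluster_id %in% drop_ids)
    keep_members <- cset$members[!(cset$members$cluster_id %in% drop_ids), ,
                                 drop = FALSE]
    old <- cset
    cset <- .new_cluster_set(keep_members, log = old$log)
    m <- match(cset$clusters$cluster_id, old$clusters$cluster_id)
    cset$clusters$centroid <- old$clusters$centroid[m]
    cset$clusters$identity_ratio <- old$clusters$identity_ratio[m]
  }
  cset$log$n_rg_prune_dropped_members <- dropped_members
  cset
}

#' Sample anchor/positive/negative triplets from a cluster set
#'
#' Anchor and positive are drawn (unordered, then randomly assigned) from
#' within one sampling cluster; the negative is drawn from a different
#' cluster sharing the anchor's reduced-graph key (negative cluster chosen
#' uniformly, then a member uniformly). Deterministic given the seed.
#' Clusters with fewer than two distinct members are skipped and counted.
#'
#' @param cset a `cluster_set` (after [prune_single_cluster_rgs()]).
#' @param config a [sampling_config()].
#' @return data.frame of triplets: `anchor`, `positive`, `negative`,
#'   `anchor_cluster`, `negative_cluster`, `rg_key`; attribute `skipped`
#'   counts clusters unable to provide an anchor/positive pair.
#' @export
sample_triplets <- function(cset, config = sampling_config()) {
  set.seed(config$rng_seed)
  cl <- cset$clusters[order(cset$clusters$cluster_id), , drop = FALSE]
  mem_by_cluster <- split(cset$members$canonical_smiles,
                          cset$members$cluster_id)
  out <- vector("list", nrow(cl))
  skipped <- 0L
  for (ci in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[ci]
    mine <- mem_by_cluster[[cid]]
    if (length(unique(mine)) < 2) { skipped <- skipped + 1L; next }
    others <- cl$cluster_id[cl$rg_key == cl$rg_key[ci] & cl$cluster_id != cid]
    if (length(others) == 0) { skipped <- skipped + 1L; next }
    k <- config$triplets_per_cluster
    anc <- character(k); pos <- character(k); neg <- character(k)
    negc <- character(k)
    for (j in seq_len(k)) {
      pair <- sample(mine, 2)
      anc[j] <- pair[1]; pos[j] <- pair[2]
      nc <- if (length(others) == 1) others else sample(others, 1)
      negc[j] <- nc
      pool <- mem_by_cluster[[nc]]
      neg[j] <- if (length(pool) == 1) pool else sample(pool, 1)
    }
    out[[ci]] <- data.frame(
      anchor = anc, positive = pos, negative = neg,
      anchor_cluster = cid, negative_cluster = negc,
      rg_key = cl$rg_key[ci], stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(anchor = character(0), positive = character(0),
                      negative = character(0), anchor_cluster = character(0),
                      negative_cluster = character(0), rg_key = character(0))
  }
  rownames(res) <- NULL
  stopifnot(all(res$anchor != res$negative), all(res$positive != res$negative))
  attr(res, "skipped") <- skipped
  res
}

#' Split triplets into training and test partitions
#'
#' @param triplets data.frame of triplets.
#' @param train_fraction fraction assigned to training (0 < f < 1).
#' @param rng_seed seed for the draw.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
train_test_split <- function(triplets, train_fraction = 0.1, rng_seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(rng_seed)
  n <- nrow(triplets)
  n_train <- round(n * train_fraction)
  idx <- sample.int(n, n_train)
  list(train = triplets[sort(idx), , drop = FALSE],
       test = triplets[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Run the full dataset-preparation pipeline
#'
#' Standardize/filter, key, cluster, centroid-annotate, identity-filter,
#' prune and sample triplets in one call.
#'
#' @param smiles raw SMILES vector.
#' @param config a [sampling_config()].
#' @param filters substructure filter sets for standardization.
#' @param scheme reduced-graph scheme.
#' @return list: `standardized` (filter_collection output), `keys`,
#'   `clusters` (final `cluster_set`), `triplets`.
#' @export
build_triplet_dataset <- function(smiles, config = sampling_config(),
                                  filters = c("REOS", "PAINS_A"),
                                  scheme = load_rg_scheme()) {
  std <- filter_collection(smiles, filters = filters)
  keys <- key_set(std$kept$canonical_smiles, scheme = scheme)
  cs <- build_clusters(keys, config)
  cs <- assign_centroids(cs)
  cs <- identity_filter(cs, config)
  cs <- prune_single_cluster_rgs(cs)
  trip <- sample_triplets(cs, config)
  list(standardized = std, keys = keys, clusters = cs, triplets = trip)
}
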