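# Molecular graph featurization for the embedding network. Atom and bond
# feature schemes follow the usual "canonical" featurizer conventions:
# element one-hot, degree, formal charge, hybridization, aromaticity and
# hydrogen count per atom; bond order, aromaticity and ring membership per
# bond. Hydrogens are implicit (encoded as counts, not nodes).

.feat_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I")

.node_feature_dim <- function() {
  length(.feat_elements) + 1L + # element one-hot (+other)
    6L + # degree 0..5+
    3L + # formal charge -1/0/+1 (clamped)
    4L + # hybridization sp/sp2/sp3/other
    1L + # aromatic flag
    5L + # H count 0..4+
    1L   # ring membership
}

.edge_feature_dim <- function() 5L # order 1/2/3 one-hot, aromatic, in-ring

.one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

.node_features <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  el <- match(at$elem, .feat_elements)
  el[is.na(el)] <- length(.feat_elements) + 1L
  deg <- pmin(at$degree, 5L) + 1L
  chg <- pmin(pmax(at$charge, -1L), 1L) + 2L
  # hybridization heuristic from bond orders around each atom
  ord_max <- rep(1L, n)
  n_double <- integer(n)
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[i, ]
      ord_max[b$a1] <- max(ord_max[b$a1], b$order)
      ord_max[b$a2] <- max(ord_max[b$a2], b$order)
      if (b$order == 2) {
        n_double[b$a1] <- n_double[b$a1] + 1L
        n_double[b$a2] <- n_double[b$a2] + 1L
      }
    }
  }
  organic <- at$elem %in% c("C", "N", "O", "S", "P")
  hyb <- ifelse(!organic, 4L,
         ifelse(ord_max >= 3 | n_double >= 2, 1L,
         ifelse(at$aromatic | n_double == 1, 2L, 3L)))
  nh <- pmin(at$nH, 4L) + 1L
  cbind(
    .one_hot(el, length(.feat_elements) + 1L),
    .one_hot(deg, 6L),
    .one_hot(chg, 3L),
    .one_hot(hyb, 4L),
    as.numeric(at$aromatic),
    .one_hot(nh, 5L),
    as.numeric(at$in_ring)
  )
}

.edge_features <- function(mol) {
  bd <- mol$bonds
  m <- nrow(bd)
  if (m == 0) return(matrix(0, 0, .edge_feature_dim()))
  ord <- pmin(pmax(bd$order, 1L), 3L)
  cbind(.one_hot(ord, 3L), as.numeric(bd$aromatic), as.numeric(bd$in_ring))
}

#' Featurize molecules as graphs for the embedding network
#'
#' @param smiles character vector of SMILES.
#' @return list of `mol_graph` objects: `n` (atom count), `node_x`
#'   (n x node-feature matrix), `edges` (m x 2 integer matrix), `edge_x`
#'   (m x edge-feature matrix), `smiles`.
#' @export
featurize <- function(smiles) {
  mols <- parse_smiles(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) stop("cannot featurize unparseable SMILES: ",
                     paste(utils::head(smiles[bad]), collapse = ", "))
  lapply(mols, function(mol) {
    g <- list(
      n = nrow(mol$atoms),
      node_x = .node_features(mol),
      edges = cbind(mol$bonds$a1, mol$bonds$a2),
      edge_x = .edge_features(mol),
      smiles = mol$smiles
    )
    class(g) <- "mol_graph"
    g
  })
}

#' Randomly ablate nodes and edges of a molecular graph
#'
#' Each node is dropped independently with `node_drop_prob` (incident edges
#' go with it); each surviving edge is dropped independently with
#' `edge_drop_prob`. The result may be disconnected or edgeless - that is
#' legal input to the network. If every node would drop, one uniformly
#' chosen node is retained.
#'
#' @param graph a `mol_graph`.
#' @param node_drop_prob,edge_drop_prob drop probabilities in `[0, 1)`
#'   (probability 1 is allowed and hits the keep-one-node guard).
#' @return ablated `mol_graph`.
#' @export
ablate <- function(graph, node_drop_prob = 0.01, edge_drop_prob = 0.05) {
  n <- graph$n
  keep <- stats::runif(n) >= node_drop_prob
  if (!any(keep)) keep[sample.int(n, 1)] <- TRUE
  if (all(keep) && edge_drop_prob == 0) return(graph)
  node_ids <- which(keep)
  remap <- match(seq_len(n), node_ids)
  m <- nrow(graph$edges)
  ekeep <- rep(FALSE, m)
  if (m > 0) {
    ekeep <- keep[graph$edges[, 1]] & keep[graph$edges[, 2]]
    ekeep[ekeep] <- stats::runif(sum(ekeep)) >= edge_drop_prob
  }
  out <- list(
    n = length(node_ids),
    node_x = graph$node_x[node_ids, , drop = FALSE],
    edges = cbind(remap[graph$edges[ekeep, 1]], remap[graph$edges[ekeep, 2]]),
    edge_x = graph$edge_x[ekeep, , drop = FALSE],
    smiles = graph$smiles
  )
  class(out) <- "mol_graph"
  out
}
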