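# Molecular abstraction keys used for clustering: the pharmacophore reduced
# graph (ring systems and acyclic groups collapsed to typed nodes), the
# Bemis-Murcko detailed frame (ring-and-linker skeleton with atom types and
# bond orders) and the Bemis-Murcko graph frame (same skeleton, every atom
# carbon, every bond single).

#' Load a reduced-graph typing scheme
#'
#' The scheme declares the node vocabulary (aromatic ring / aliphatic ring /
#' acyclic group), the donor and acceptor assignment rules and the grouping
#' conventions. It is a versioned data asset: alternative schemes can be
#' supplied by path.
#'
#' @param path path to a scheme JSON; default loads the shipped scheme.
#' @return scheme as a nested list.
#' @export
load_rg_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rg_scheme_v1.json", package = "moltriplet")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.atom_features <- function(atoms, scheme) {
  dr <- scheme$donor_rule
  ar <- scheme$acceptor_rule
  donor <- atoms$elem %in% dr$elements &
    (!isTRUE(dr$requires_hydrogen) | atoms$nH >= 1)
  acceptor <- atoms$elem %in% ar$elements & atoms$charge <= ar$max_formal_charge
  if (isTRUE(ar$exclude_aromatic_nh)) {
    acceptor <- acceptor & !(atoms$elem == "N" & atoms$aromatic & atoms$nH >= 1)
  }
  list(donor = donor, acceptor = acceptor)
}

# Partition atoms into reduced-graph groups. Returns integer group id per
# atom plus per-group ring/aromatic flags.
.rg_groups <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  na <- nrow(at)
  gid <- integer(na)
  ring_groups <- 0L
  # ring systems: components of the ring-bond subgraph
  if (any(bd$in_ring)) {
    rb <- bd[bd$in_ring, , drop = FALSE]
    g <- igraph::graph_from_edgelist(cbind(rb$a1, rb$a2), directed = FALSE)
    if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    ring_comp <- unique(comp[at$in_ring])
    for (k in seq_along(ring_comp)) {
      gid[at$in_ring & comp == ring_comp[k]] <- k
    }
    ring_groups <- length(ring_comp)
  }
  # acyclic groups: components of the subgraph induced by non-ring atoms
  acyc <- which(gid == 0L)
  if (length(acyc) > 0) {
    sub_bd <- bd[bd$a1 %in% acyc & bd$a2 %in% acyc, , drop = FALSE]
    idx <- match(seq_len(na), acyc) # position within acyc or NA
    g <- igraph::make_empty_graph(n = length(acyc), directed = FALSE)
    if (nrow(sub_bd) > 0) {
      g <- igraph::add_edges(g, rbind(idx[sub_bd$a1], idx[sub_bd$a2]))
    }
    comp <- igraph::components(g)$membership
    gid[acyc] <- ring_groups + comp
  }
  ngroups <- max(gid)
  is_ring_group <- vapply(seq_len(ngroups),
                          function(k) any(at$in_ring[gid == k]), logical(1))
  list(gid = gid, is_ring = is_ring_group)
}

#' Compute the pharmacophore reduced graph of a molecule
#'
#' Ring systems (fused or spiro systems sharing an atom merge) collapse to
#' one node each; connected groups of acyclic atoms collapse to one node
#' each; single-atom terminal substituents attached to exactly one ring
#' system are absorbed into that ring node. Nodes are typed by ring
#' character (aromatic ring / aliphatic ring / acyclic) and hydrogen-bond
#' donor/acceptor presence; edges connect nodes whose atom groups are
#' bonded.
#'
#' @param smiles a single SMILES string (or a parsed mol object).
#' @param scheme typing scheme from [load_rg_scheme()].
#' @return object of class `reduced_graph`: list with `nodes` (data.frame:
#'   ring_class, donor, acceptor, label), `edges` (two-column matrix) and
#'   `key` (canonical string).
#' @export
reduced_graph <- function(smiles, scheme = load_rg_scheme()) {
  mol <- if (is.character(smiles)) parse_smiles(smiles)[[1]] else smiles
  if (is.null(mol)) stop("unparseable SMILES")
  if (grepl(".", mol$smiles, fixed = TRUE)) {
    stop("reduced_graph expects a connected (parent) structure")
  }
  at <- mol$atoms
  bd <- mol$bonds
  grp <- .rg_groups(mol)
  gid <- grp$gid
  feats <- .atom_features(at, scheme)
  ngroups <- length(grp$is_ring)
  # group adjacency (before merging)
  cross <- bd[gid[bd$a1] != gid[bd$a2], , drop = FALSE]
  if (nrow(cross) > 0) {
    adj <- unique(cbind(pmin(gid[cross$a1], gid[cross$a2]),
                        pmax(gid[cross$a1], gid[cross$a2])))
  } else {
    adj <- matrix(integer(0), 0, 2)
  }
  # absorb single-atom terminal substituents into their ring neighbour
  merge_to <- seq_len(ngroups)
  if (isTRUE(scheme$grouping$merge_single_atom_terminal_substituents) &&
      nrow(adj) > 0) {
    for (k in seq_len(ngroups)) {
      if (grp$is_ring[k]) next
      if (sum(gid == k) != 1) next
      nbr <- unique(c(adj[adj[, 1] == k, 2], adj[adj[, 2] == k, 1]))
      if (length(nbr) == 1 && grp$is_ring[nbr]) merge_to[k] <- nbr
    }
  }
  gid <- merge_to[gid]
  keep <- sort(unique(gid))
  ratom <- match(gid, keep) # relabeled group id per atom
  nodes <- data.frame(
    ring_class = ifelse(
      vapply(keep, function(k) any(at$in_ring[gid == k]), logical(1)),
      ifelse(vapply(keep, function(k) any(at$aromatic[gid == k]), logical(1)),
             "Ar", "Al"),
      "Ac"),
    donor = vapply(keep, function(k) any(feats$donor[gid == k]), logical(1)),
    acceptor = vapply(keep, function(k) any(feats$acceptor[gid == k]), logical(1)),
    stringsAsFactors = FALSE
  )
  nodes$label <- paste0(
    nodes$ring_class,
    ifelse(nodes$donor & nodes$acceptor, ".DA",
           ifelse(nodes$donor, ".D", ifelse(nodes$acceptor, ".A", "")))
  )
  cross <- bd[ratom[bd$a1] != ratom[bd$a2], , drop = FALSE]
  if (nrow(cross) > 0) {
    ep <- cbind(pmin(ratom[cross$a1], ratom[cross$a2]),
                pmax(ratom[cross$a1], ratom[cross$a2]))
    edges <- unique(ep)
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  out <- list(nodes = nodes, edges = edges)
  out$key <- .rg_canonical_key(nodes$label, edges)
  class(out) <- "reduced_graph"
  out
}

# canonical string for a typed graph via BLISS canonical numbering with
# node-type colours
.rg_canonical_key <- function(labels, edges) {
  n <- length(labels)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  colors <- as.integer(factor(labels,
    levels = c("Ar", "Ar.D", "Ar.A", "Ar.DA",
               "Al", "Al.D", "Al.A", "Al.DA",
               "Ac", "Ac.D", "Ac.A", "Ac.DA")))
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  new_lab <- character(n)
  new_lab[perm] <- labels
  if (nrow(edges) > 0) {
    e <- cbind(perm[edges[, 1]], perm[edges[, 2]])
    e <- t(apply(e, 1, sort))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    estr <- paste(paste0(e[, 1], "-", e[, 2]), collapse = ",")
  } else estr <- ""
  paste0(paste(new_lab, collapse = ","), "|", estr)
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat("reduced graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("key:", x$key, "\n")
  invisible(x)
}

# indices of scaffold atoms (rings + linkers): iteratively prune terminal
# non-ring atoms
.scaffold_atoms <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  if (!any(at$in_ring)) return(integer(0))
  alive <- rep(TRUE, nrow(at))
  repeat {
    deg <- integer(nrow(at))
    act <- bd[alive[bd$a1] & alive[bd$a2], , drop = FALSE]
    if (nrow(act) > 0) {
      tab <- table(c(act$a1, act$a2))
      deg[as.integer(names(tab))] <- as.integer(tab)
    }
    drop <- alive & !at$in_ring & deg <= 1
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}

#' Bemis-Murcko frames of a molecule
#'
#' The detailed frame is the molecule with all side chains pruned (terminal
#' non-ring atoms removed iteratively until only rings and linkers remain),
#' keeping atom types and bond orders; the graph frame is the same skeleton
#' with every atom anonymized to carbon and every bond to a single bond.
#' Acyclic molecules have empty frames.
#'
#' @param smiles a single SMILES string (or a parsed mol object).
#' @return list with `detailed_frame`, `graph_frame` (canonical SMILES,
#'   `""` for acyclic molecules) and `is_acyclic`.
#' @export
murcko_frames <- function(smiles) {
  mol <- if (is.character(smiles)) parse_smiles(smiles)[[1]] else smiles
  if (is.null(mol)) stop("unparseable SMILES")
  sc <- .scaffold_atoms(mol)
  if (length(sc) == 0) {
    return(list(detailed_frame = "", graph_frame = "", is_acyclic = TRUE))
  }
  gr <- .frame_graphs(mol, sc)
  sm <- .graphs_to_smiles(list(gr$detailed, gr$graph))
  list(detailed_frame = sm[1], graph_frame = sm[2], is_acyclic = FALSE)
}

.frame_graphs <- function(mol, sc) {
  bd <- mol$bonds
  sub <- bd[bd$a1 %in% sc & bd$a2 %in% sc, , drop = FALSE]
  remap <- match(seq_len(nrow(mol$atoms)), sc)
  detailed <- list(
    elem = mol$atoms$elem[sc],
    bonds = data.frame(a1 = remap[sub$a1], a2 = remap[sub$a2],
                       order = sub$order)
  )
  graph <- list(
    elem = rep("C", length(sc)),
    bonds = data.frame(a1 = remap[sub$a1], a2 = remap[sub$a2],
                       order = rep(1L, nrow(sub)))
  )
  list(detailed = detailed, graph = graph)
}

#' Cluster key set for a collection of molecules
#'
#' Computes, for each molecule, the reduced-graph key, the graph-frame key
#' and the detailed-frame key. All three are deterministic functions of the
#' canonical SMILES. Frame canonicalization is batched through a single
#' conversion call.
#'
#' @param smiles character vector of standardized (KEEP) canonical SMILES.
#' @param scheme reduced-graph typing scheme.
#' @return data.frame: `canonical_smiles`, `rg_key`, `gf_key`, `df_key`.
#' @export
key_set <- function(smiles, scheme = load_rg_scheme()) {
  n <- length(smiles)
  if (n == 0) {
    return(data.frame(canonical_smiles = character(0), rg_key = character(0),
                      gf_key = character(0), df_key = character(0)))
  }
  mols <- parse_smiles(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) stop("unparseable SMILES in key_set: ",
                     paste(utils::head(smiles[bad]), collapse = ", "))
  rg <- vapply(mols, function(m) reduced_graph(m, scheme)$key, character(1))
  frame_jobs <- list()
  job_of <- matrix(NA_integer_, n, 2) # detailed, graph job index
  for (i in seq_len(n)) {
    sc <- .scaffold_atoms(mols[[i]])
    if (length(sc) == 0) next
    gr <- .frame_graphs(mols[[i]], sc)
    frame_jobs[[length(frame_jobs) + 1L]] <- gr$detailed
    job_of[i, 1] <- length(frame_jobs)
    frame_jobs[[length(frame_jobs) + 1L]] <- gr$graph
    job_of[i, 2] <- length(frame_jobs)
  }
  fr <- .graphs_to_smiles(frame_jobs)
  df_key <- ifelse(is.na(job_of[, 1]), "", fr[job_of[, 1]])
  gf_key <- ifelse(is.na(job_of[, 2]), "", fr[job_of[, 2]])
  data.frame(canonical_smiles = smiles, rg_key = rg,
             gf_key = gf_key, df_key = df_key, stringsAsFactors = FALSE)
}
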