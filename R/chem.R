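# OpenBabel-backed chemistry primitives. All operations are batch-oriented:
# one conversion call (ChemmineOB) or one obabel process per batch/pattern,
# with record identity carried through molecule titles.

.ob_opts <- function(...) {
  nm <- c(...)
  data.frame(names = nm, args = rep("", length(nm)))
}

.obabel_bin <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH")
  p
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparseable inputs yield
#' `NA`. Explicit hydrogens are removed so that equivalent spellings map to
#' one canonical string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  src <- paste(paste0(smiles, " t", seq_along(smiles)), collapse = "\n")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", src, options = .ob_opts("d", "e"))
  )
  .map_titled_smiles(out, length(smiles))
}

# parse "smiles\ttN" lines back into positional order
.map_titled_smiles <- function(out, n) {
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    idx <- suppressWarnings(as.integer(sub("^t", "", trimws(parts[2]))))
    if (!is.na(idx) && idx >= 1 && idx <= n) res[idx] <- parts[1]
  }
  res
}

#' Neutralize formal charges where chemically valid
#'
#' Applies OpenBabel's neutralize operation (protonates/deprotonates charged
#' atoms that admit a neutral form; quaternary centres are left unchanged).
#'
#' @param smiles character vector of SMILES.
#' @return character vector of neutralized canonical SMILES (`NA` on failure).
#' @export
neutralize_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  src <- paste(paste0(smiles, " t", seq_along(smiles)), collapse = "\n")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", src,
                              options = .ob_opts("d", "neutralize", "e"))
  )
  .map_titled_smiles(out, length(smiles))
}

# ---- molblock parsing ----------------------------------------------------

# Minimal tolerant V2000 reader (handles 0-atom/0-bond blocks, M CHG, M ISO).
.parse_molblock <- function(lines) {
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  elem <- character(natoms)
  if (natoms > 0) {
    at <- lines[4 + seq_len(natoms)]
    elem <- trimws(substr(at, 32, 34))
  }
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  charge <- integer(natoms)
  isotope <- integer(natoms)
  prop <- grep("^M  (CHG|ISO)", lines, value = TRUE)
  for (ln in prop) {
    kind <- substr(ln, 4, 6)
    k <- as.integer(substr(ln, 7, 9))
    for (j in seq_len(k)) {
      off <- 10 + (j - 1) * 8
      aidx <- as.integer(substr(ln, off, off + 3))
      val <- as.integer(substr(ln, off + 4, off + 7))
      if (kind == "CHG") charge[aidx] <- val
      if (kind == "ISO") isotope[aidx] <- val
    }
  }
  list(elem = elem, charge = charge, isotope = isotope, bonds = bonds)
}

# Scan SMILES atom tokens in order; returns data.frame(token, aromatic).
# OpenBabel writes SDF atoms in SMILES token order, which lets aromaticity
# be read off the canonical SMILES.
.smiles_atom_tokens <- function(smi) {
  pat <- "\\[[^]]+\\]|Cl|Br|[BCNOPSFI]|[bcnops]|\\*"
  m <- gregexpr(pat, smi)[[1]]
  if (m[1] == -1) return(data.frame(token = character(0), aromatic = logical(0)))
  tok <- regmatches(smi, gregexpr(pat, smi))[[1]]
  arom <- vapply(tok, function(t) {
    if (startsWith(t, "[")) {
      body <- sub("^\\[[0-9]*", "", t)
      grepl("^[a-z]", body)
    } else {
      grepl("^[a-z]", t)
    }
  }, logical(1), USE.NAMES = FALSE)
  data.frame(token = tok, aromatic = arom)
}

# standard average atomic weights (IUPAC 2021, conventional values)
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904, I = 126.904
)

# default valences; elements absent here get NA (no implicit H, no valence check)
.default_valences <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.implicit_h <- function(elem, charge, bosum) {
  vals <- .default_valences[[elem]]
  if (is.null(vals)) return(0L)
  eff <- switch(elem,
    C = vals - abs(charge),
    N = , P = vals + charge,
    O = , S = vals + charge,
    vals - abs(charge)
  )
  eff <- eff[eff >= bosum]
  if (length(eff) == 0) return(0L)
  as.integer(min(eff) - bosum)
}

.max_valence_ok <- function(elem, charge, bosum) {
  vals <- .default_valences[[elem]]
  if (is.null(vals)) return(TRUE) # unknown elements handled by element filter
  eff <- switch(elem,
    C = vals - abs(charge),
    N = , P = vals + charge,
    O = , S = vals + charge,
    vals - abs(charge)
  )
  bosum <= max(eff)
}

#' Parse SMILES into annotated molecular graphs
#'
#' Batch-parses SMILES via OpenBabel into a per-molecule atom/bond table with
#' element, formal charge, isotope label, aromaticity, implicit hydrogen
#' count and ring membership.
#'
#' @param smiles character vector of (preferably canonical) SMILES.
#' @return list of mol objects (`NULL` where parsing failed): each a list with
#'   `atoms` (data.frame: elem, charge, isotope, aromatic, nH, in_ring,
#'   degree), `bonds` (data.frame: a1, a2, order, aromatic, in_ring) and
#'   `smiles`.
#' @export
parse_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(list())
  src <- paste(paste0(smiles, " t", seq_along(smiles)), collapse = "\n")
  sdf <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", src, options = .ob_opts("e"))
  )
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- vector("list", n)
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    if (length(lines) > 0 && !nzchar(lines[1])) lines <- lines[-1]
    idx <- suppressWarnings(as.integer(sub("^t", "", trimws(lines[1]))))
    if (is.na(idx) || idx < 1 || idx > n) next
    pb <- .parse_molblock(lines)
    out[[idx]] <- .annotate_mol(pb, smiles[idx])
  }
  out
}

.annotate_mol <- function(pb, smi) {
  na <- length(pb$elem)
  toks <- .smiles_atom_tokens(smi)
  aromatic <- if (nrow(toks) == na) toks$aromatic else rep(FALSE, na)
  bonds <- pb$bonds
  in_ring_atom <- rep(FALSE, na)
  bond_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0 && na > 1) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
    if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
    br <- igraph::bridges(g)
    bond_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_atoms <- unique(c(bonds$a1[bond_ring], bonds$a2[bond_ring]))
    in_ring_atom[ring_atoms] <- TRUE
  }
  bosum <- numeric(na)
  degree <- integer(na)
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      o <- bonds$order[i]
      bosum[bonds$a1[i]] <- bosum[bonds$a1[i]] + o
      bosum[bonds$a2[i]] <- bosum[bonds$a2[i]] + o
      degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
      degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
    }
  }
  nH <- integer(na)
  val_ok <- logical(na)
  for (i in seq_len(na)) {
    nH[i] <- .implicit_h(pb$elem[i], pb$charge[i], bosum[i])
    val_ok[i] <- .max_valence_ok(pb$elem[i], pb$charge[i], bosum[i])
  }
  bond_arom <- bond_ring & aromatic[bonds$a1] & aromatic[bonds$a2]
  list(
    atoms = data.frame(
      elem = pb$elem, charge = pb$charge, isotope = pb$isotope,
      aromatic = aromatic, nH = nH, in_ring = in_ring_atom,
      degree = degree, valence_ok = val_ok,
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      a1 = bonds$a1, a2 = bonds$a2, order = bonds$order,
      aromatic = bond_arom, in_ring = bond_ring
    ),
    smiles = smi
  )
}

#' Average molecular weight of a parsed molecule
#' @param mol a mol object from [parse_smiles()].
#' @return molecular weight in daltons (implicit hydrogens included).
#' @export
mol_weight <- function(mol) {
  w <- .atomic_weights[mol$atoms$elem]
  w[is.na(w)] <- 0
  sum(w) + sum(mol$atoms$nH) * .atomic_weights[["H"]]
}

# ---- molblock writing (for scaffold frames) ------------------------------

.fmt_int3 <- function(x) formatC(x, width = 3, format = "d")

.graph_to_molblock <- function(elem, bonds, title = "") {
  na <- length(elem)
  nb <- nrow(bonds)
  hdr <- c(title, " moltriplet", "",
           paste0(.fmt_int3(na), .fmt_int3(nb),
                  "  0  0  0  0  0  0  0  0999 V2000"))
  atom_lines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", elem)
  bond_lines <- if (nb > 0) {
    sprintf("%s%s%s  0  0  0  0", .fmt_int3(bonds$a1), .fmt_int3(bonds$a2),
            .fmt_int3(bonds$order))
  } else character(0)
  paste(c(hdr, atom_lines, bond_lines, "M  END", "$$$$"), collapse = "\n")
}

# Batch-convert skeleton graphs to canonical SMILES. `graphs` is a list of
# list(elem=, bonds=) entries; returns character vector (NA on failure).
.graphs_to_smiles <- function(graphs) {
  n <- length(graphs)
  if (n == 0) return(character(0))
  blocks <- vapply(seq_len(n), function(i) {
    .graph_to_molblock(graphs[[i]]$elem, graphs[[i]]$bonds, paste0("t", i))
  }, character(1))
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", paste(blocks, collapse = "\n"),
                              options = .ob_opts("e"))
  )
  .map_titled_smiles(out, n)
}

# ---- fingerprints --------------------------------------------------------

#' Extended-connectivity fingerprints via OpenBabel
#'
#' Computes hashed circular fingerprints (4096-bit) for a batch of SMILES in
#' a single obabel process.
#'
#' @param smiles character vector of SMILES.
#' @param type fingerprint name: "ECFP4" (radius 2) or "ECFP0" (radius 0).
#' @return sparse logical matrix (`Matrix::lgCMatrix`), one row per input;
#'   rows of unparseable molecules are empty.
#' @export
ecfp_fingerprints <- function(smiles, type = c("ECFP4", "ECFP0")) {
  type <- match.arg(type)
  n <- length(smiles)
  nbits <- 4096L
  if (n == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(0L, nbits)))
  }
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste0(smiles, " t", seq_along(smiles)), inp)
  out <- suppressWarnings(
    system2(.obabel_bin(), c(shQuote(inp), "-ofpt", paste0("-xf", type), "-xh"),
            stdout = TRUE, stderr = FALSE)
  )
  .parse_fpt_hex(out, n, nbits)
}

# bit positions set in a hex nibble (value 0..15), high bit first
.nibble_positions <- lapply(0:15, function(v) which(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0))

# hex string -> 1-based bit positions (consistent bijection; absolute bit
# numbering is irrelevant as long as it is identical across molecules)
.hex_to_positions <- function(hx) {
  nib <- strtoi(strsplit(hx, "", fixed = TRUE)[[1]], 16L)
  pos <- .nibble_positions[nib + 1]
  offs <- (seq_along(nib) - 1L) * 4L
  unlist(mapply(function(p, o) p + o, pos, offs, SIMPLIFY = FALSE),
         use.names = FALSE)
}

.parse_fpt_hex <- function(lines, n, nbits) {
  ii <- integer(0); jj <- integer(0)
  cur <- NA_integer_
  hexbuf <- character(0)
  records <- list()
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.na(cur) && length(hexbuf) > 0) {
        records[[length(records) + 1L]] <- list(idx = cur, hex = hexbuf)
      }
      hexbuf <- character(0)
      tt <- sub("^>\\s*(t[0-9]+).*$", "\\1", ln)
      cur <- suppressWarnings(as.integer(sub("^t", "", tt)))
    } else if (grepl("^[0-9a-f ]+$", ln) && nzchar(trimws(ln))) {
      hexbuf <- c(hexbuf, gsub(" ", "", ln, fixed = TRUE))
    }
  }
  if (!is.na(cur) && length(hexbuf) > 0) {
    records[[length(records) + 1L]] <- list(idx = cur, hex = hexbuf)
  }
  for (r in records) {
    pos <- .hex_to_positions(paste(r$hex, collapse = ""))
    ii <- c(ii, rep(r$idx, length(pos)))
    jj <- c(jj, pos)
  }
  keep <- !is.na(ii) & ii >= 1 & ii <= n & jj >= 1 & jj <= nbits
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], dims = c(n, as.integer(nbits)))
}

#' Tanimoto similarity between fingerprint sets
#'
#' @param fp1,fp2 sparse logical fingerprint matrices (rows = molecules);
#'   `fp2 = NULL` computes all pairwise similarities within `fp1`.
#' @return dense numeric similarity matrix.
#' @export
tanimoto_similarity <- function(fp1, fp2 = NULL) {
  f1 <- methods::as(fp1, "dMatrix")
  f2 <- if (is.null(fp2)) f1 else methods::as(fp2, "dMatrix")
  inter <- as.matrix(Matrix::tcrossprod(f1, f2))
  n1 <- Matrix::rowSums(f1)
  n2 <- Matrix::rowSums(f2)
  un <- outer(n1, n2, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  sim
}

# ---- SMARTS screening ----------------------------------------------------

#' Screen molecules against SMARTS patterns
#'
#' Runs one obabel process per pattern over the whole batch; molecules get
#' explicit hydrogens before matching so that patterns with explicit `[#1]`
#' atoms (as in the published PAINS definitions) behave as intended.
#'
#' @param smiles character vector of SMILES.
#' @param patterns named character vector of SMARTS.
#' @return logical matrix, `length(smiles)` x `length(patterns)`.
#' @export
smarts_screen <- function(smiles, patterns) {
  n <- length(smiles)
  hits <- matrix(FALSE, n, length(patterns),
                 dimnames = list(NULL, names(patterns)))
  if (n == 0 || length(patterns) == 0) return(hits)
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste0(smiles, " t", seq_along(smiles)), inp)
  for (k in seq_along(patterns)) {
    out <- suppressWarnings(
      system2(.obabel_bin(),
              c(shQuote(inp), "-osmi", "-h", paste0("-s", shQuote(patterns[[k]]))),
              stdout = TRUE, stderr = FALSE)
    )
    if (length(out) == 0) next
    tt <- sub("^.*\t", "", out)
    idx <- suppressWarnings(as.integer(sub("^t", "", trimws(tt))))
    idx <- idx[!is.na(idx)]
    hits[idx, k] <- TRUE
  }
  hits
}
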