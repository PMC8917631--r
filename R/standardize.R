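# Standardization of raw SMILES records into parent structures with
# keep/discard verdicts: parent = largest organic fragment, charges
# neutralized where chemically valid; structural checks (valence, wildcard
# bonds, isotopes, element whitelist, molecular weight) and substructure
# alerts (REOS, PAINS A) accumulate into per-record reason codes.

.element_whitelist <- c("N", "O", "C", "S", "F", "Cl", "Br", "I")
.mw_cutoff <- 650

.reason_codes <- c("PARSE_FAIL", "BAD_VALENCE", "BAD_BOND", "ISOTOPE",
                   "ELEMENT", "MW", "REOS", "PAINS")

.load_alerts <- function(which = c("REOS", "PAINS_A")) {
  which <- match.arg(which)
  file <- switch(which,
    REOS = "reos_alerts_v1.tsv",
    PAINS_A = "pains_a_v1.tsv"
  )
  path <- system.file("extdata", file, package = "moltriplet")
  if (!nzchar(path)) stop("alert file not found: ", file)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pats <- vapply(parts, `[`, character(1), 2)
  names(pats) <- vapply(parts, `[`, character(1), 1)
  pats
}

# pick the largest organic fragment of a (canonical) SMILES; ties broken by
# heavy-atom count then lexicographically for determinism
.largest_organic_fragment <- function(cansmi) {
  frags <- strsplit(cansmi, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(cansmi)
  natoms <- vapply(frags, function(f) nrow(.smiles_atom_tokens(f)), integer(1))
  organic <- vapply(frags, function(f) {
    any(grepl("C|c", .smiles_atom_tokens(f)$token))
  }, logical(1))
  pool <- if (any(organic)) which(organic) else seq_along(frags)
  pool <- pool[order(-natoms[pool], frags[pool])]
  frags[pool[1]]
}

#' Standardize a collection of SMILES records
#'
#' Vectorized standardization: canonicalizes each record, extracts the parent
#' structure (largest organic fragment, salts/solvents stripped), neutralizes
#' formal charges where a neutral form exists, and applies all structural
#' checks and substructure filters. Reasons accumulate; no check
#' short-circuits another (except that an unparseable record can only carry
#' `PARSE_FAIL`).
#'
#' @param smiles character vector of raw SMILES.
#' @param ids optional record identifiers (defaults to positions).
#' @param filters substructure filter sets to apply, a subset of
#'   `c("REOS", "PAINS_A")`.
#' @return data.frame with one row per record: `source_id`, `input_smiles`,
#'   `canonical_smiles`, `mol_weight`, `heavy_atom_count`, `element_set`
#'   (comma-joined), `verdict` ("KEEP"/"DISCARD") and `discard_reasons`
#'   (comma-joined reason codes).
#' @export
standardize_collection <- function(smiles, ids = NULL,
                                   filters = c("REOS", "PAINS_A")) {
  n <- length(smiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  stopifnot(length(ids) == n)
  bad <- !nzchar(trimws(smiles))
  if (any(bad)) stop("empty SMILES at record(s): ",
                     paste(utils::head(which(bad)), collapse = ", "))
  res <- data.frame(
    source_id = ids, input_smiles = smiles,
    canonical_smiles = NA_character_, mol_weight = NA_real_,
    heavy_atom_count = NA_integer_, element_set = NA_character_,
    verdict = "DISCARD", discard_reasons = "",
    stringsAsFactors = FALSE
  )
  cans <- canonical_smiles(smiles)
  reasons <- vector("list", n)
  parsed_idx <- which(!is.na(cans))
  for (i in which(is.na(cans))) reasons[[i]] <- "PARSE_FAIL"
  if (length(parsed_idx) > 0) {
    parents <- vapply(cans[parsed_idx], .largest_organic_fragment,
                      character(1), USE.NAMES = FALSE)
    neut <- neutralize_smiles(parents)
    # a fragment that fails to re-parse after neutralization keeps its
    # pre-neutralization form (should not occur for valid input)
    parents <- ifelse(is.na(neut), parents, neut)
    mols <- parse_smiles(parents)
    for (k in seq_along(parsed_idx)) {
      i <- parsed_idx[k]
      mol <- mols[[k]]
      if (is.null(mol)) { reasons[[i]] <- "PARSE_FAIL"; next }
      at <- mol$atoms
      res$canonical_smiles[i] <- parents[k]
      res$mol_weight[i] <- mol_weight(mol)
      res$heavy_atom_count[i] <- nrow(at)
      res$element_set[i] <- paste(sort(unique(at$elem)), collapse = ",")
      rs <- character(0)
      if (!all(at$valence_ok)) rs <- c(rs, "BAD_VALENCE")
      if (any(at$elem %in% c("", "*", "R", "A")) ||
          any(mol$bonds$order < 1 | mol$bonds$order > 3)) {
        rs <- c(rs, "BAD_BOND")
      }
      if (any(at$isotope > 0)) rs <- c(rs, "ISOTOPE")
      if (!all(at$elem %in% .element_whitelist)) rs <- c(rs, "ELEMENT")
      if (res$mol_weight[i] > .mw_cutoff) rs <- c(rs, "MW")
      reasons[[i]] <- rs
    }
    # substructure alerts on records that parsed (batch, one pass per set)
    ok <- parsed_idx[!vapply(mols, is.null, logical(1))]
    if (length(ok) > 0 && length(filters) > 0) {
      sm <- res$canonical_smiles[ok]
      for (fset in filters) {
        code <- if (fset == "PAINS_A") "PAINS" else fset
        pats <- .load_alerts(fset)
        hit <- rowSums(smarts_screen(sm, pats)) > 0
        for (k in which(hit)) {
          i <- ok[k]
          reasons[[i]] <- c(reasons[[i]], code)
        }
      }
    }
  }
  for (i in seq_len(n)) {
    rs <- intersect(.reason_codes, reasons[[i]]) # canonical order
    res$discard_reasons[i] <- paste(rs, collapse = ",")
    res$verdict[i] <- if (length(rs) == 0) "KEEP" else "DISCARD"
  }
  res
}

#' Standardize a single SMILES record
#'
#' @param smiles a single SMILES string.
#' @param source_id optional identifier.
#' @param filters substructure filter sets (see [standardize_collection()]).
#' @return one-row data.frame as in [standardize_collection()].
#' @export
standardize_molecule <- function(smiles, source_id = "1",
                                 filters = c("REOS", "PAINS_A")) {
  standardize_collection(smiles, ids = source_id, filters = filters)
}

#' Apply substructure filters to a molecule
#'
#' @param smiles a single parseable SMILES string.
#' @param filter_set which filter sets to apply: `"REOS"`, `"PAINS_A"` or both.
#' @return character vector of triggered filter codes (possibly empty).
#' @export
apply_substructure_filters <- function(smiles,
                                       filter_set = c("REOS", "PAINS_A")) {
  if (!all(filter_set %in% c("REOS", "PAINS_A"))) {
    stop("unknown filter set: ",
         paste(setdiff(filter_set, c("REOS", "PAINS_A")), collapse = ", "))
  }
  if (is.na(canonical_smiles(smiles))) stop("unparseable SMILES: ", smiles)
  out <- character(0)
  for (fset in filter_set) {
    pats <- .load_alerts(fset)
    if (any(smarts_screen(smiles, pats))) {
      out <- c(out, if (fset == "PAINS_A") "PAINS_A" else fset)
    }
  }
  out
}

#' Filter a SMILES collection into kept standardized parents
#'
#' Runs [standardize_collection()], deduplicates kept records on canonical
#' SMILES (first occurrence wins) and assembles a filter report with
#' per-reason counts.
#'
#' @param smiles character vector of raw SMILES (or a file path, see
#'   [read_smiles_file()]).
#' @param ids optional record identifiers.
#' @param filters substructure filter sets.
#' @return list with `kept` (deduplicated data.frame of KEEP records),
#'   `all` (the full standardization table) and `report` (list: `n_input`,
#'   `n_kept`, `n_discarded`, `n_duplicates`, `reason_counts`).
#' @export
filter_collection <- function(smiles, ids = NULL,
                              filters = c("REOS", "PAINS_A")) {
  if (length(smiles) == 1 && file.exists(smiles)) {
    rec <- read_smiles_file(smiles)
    smiles <- rec$smiles
    if (is.null(ids)) ids <- rec$id
  }
  if (length(smiles) == 0) {
    report <- list(n_input = 0L, n_kept = 0L, n_discarded = 0L,
                   n_duplicates = 0L,
                   reason_counts = stats::setNames(rep(0L, length(.reason_codes)),
                                                   .reason_codes))
    return(list(kept = data.frame(), all = data.frame(), report = report))
  }
  tab <- standardize_collection(smiles, ids = ids, filters = filters)
  kept <- tab[tab$verdict == "KEEP", , drop = FALSE]
  dup <- duplicated(kept$canonical_smiles)
  n_dup <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  reason_counts <- vapply(.reason_codes, function(rc) {
    sum(vapply(strsplit(tab$discard_reasons, ",", fixed = TRUE),
               function(x) rc %in% x, logical(1)))
  }, integer(1))
  report <- list(
    n_input = nrow(tab),
    n_kept = nrow(kept),
    n_discarded = sum(tab$verdict == "DISCARD"),
    n_duplicates = n_dup,
    reason_counts = reason_counts
  )
  list(kept = kept, all = tab, report = report)
}

#' Read a SMILES file
#'
#' Reads whitespace-separated `.smi` (`SMILES [name]`) or CSV with a SMILES
#' column.
#'
#' @param path input file path.
#' @param smiles_col CSV column holding SMILES (default: a column named
#'   `smiles`, case-insensitive; ignored for `.smi`).
#' @return data.frame with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path, smiles_col = NULL) {
  if (!file.exists(path)) stop("cannot open input file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    col <- smiles_col
    if (is.null(col)) {
      hit <- which(tolower(names(tab)) == "smiles")
      if (length(hit) == 0) stop("no 'smiles' column in ", path)
      col <- names(tab)[hit[1]]
    }
    if (!col %in% names(tab)) stop("no column '", col, "' in ", path)
    id <- if ("id" %in% tolower(names(tab))) {
      as.character(tab[[which(tolower(names(tab)) == "id")[1]]])
    } else as.character(seq_len(nrow(tab)))
    return(data.frame(id = id, smiles = tab[[col]], stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  bad <- grep("^\\s", lines)
  if (length(bad) > 0) stop("malformed record at line ", bad[1], " of ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else as.character(i)
    }, character(1)),
    smiles = vapply(parts, `[`, character(1), 1),
    stringsAsFactors = FALSE
  )
}
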