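# Deterministic synthetic SMILES libraries with controlled scaffold/cluster
# structure. Scaffold templates are enumerated against a substituent set so
# that the resulting collection carries non-trivial reduced-graph / frame
# cluster structure: templates come in pairs sharing a reduced graph but
# differing in ring size or ring composition (5- vs 6-membered rings,
# carbocycle vs heterocycle, one- vs two-ring systems), which is exactly the
# structure negative sampling needs.

#' Default scaffold templates
#'
#' Each template is a SMILES with `(*)` substitution slots. Templates are
#' grouped in reduced-graph-sharing families: benzene/thiophene (aromatic,
#' featureless), cyclohexane/cyclopentane/decalin (aliphatic), phenol/
#' hydroxythiophene (aromatic donor+acceptor), pyridine/oxazole (aromatic
#' acceptor), biphenyl/phenylthiophene (two aromatic rings), cyclohexanol/
#' cyclopentanol (aliphatic donor+acceptor).
#'
#' @return data.frame with columns `name` and `template`.
#' @export
default_scaffolds <- function() {
  data.frame(
    name = c("benzene", "thiophene",
             "cyclohexane", "cyclopentane", "decalin",
             "phenol", "hydroxythiophene",
             "pyridine", "oxazole",
             "biphenyl", "phenylthiophene",
             "cyclohexanol", "cyclopentanol"),
    template = c(
      "c1c(*)c(*)c(*)c(*)c1", "c1c(*)c(*)c(*)s1",
      "C1CC(*)C(*)CC(*)C1(*)", "C1C(*)C(*)C(*)C1(*)", "C1CC(*)C2CC(*)C(*)CC2C1",
      "Oc1cc(*)c(*)cc1", "Oc1c(*)c(*)cs1",
      "c1c(*)c(*)c(*)nc1", "c1(*)oc(*)nc1(*)",
      "c1ccc(cc1)-c1cc(*)c(*)cc1", "c1ccc(cc1)-c1c(*)c(*)cs1",
      "OC1CC(*)C(*)CC1(*)", "OC1C(*)C(*)CC1(*)"
    ),
    # halogen substituents on sp3 ring carbons would (correctly) trigger the
    # reactive alkyl-halide alert, so aliphatic scaffolds exclude them
    allow_halogens = c(TRUE, TRUE,
                       FALSE, FALSE, FALSE,
                       TRUE, TRUE,
                       TRUE, TRUE,
                       TRUE, TRUE,
                       FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Library generation specification
#'
#' @param scaffolds data.frame of scaffold templates (`name`, `template`
#'   with `(*)` slots).
#' @param substituents substituent fragments spliced into slots; `""` means
#'   unsubstituted, so the number of substitutions per molecule ranges from
#'   0 to the slot count.
#' @param n_per_scaffold maximum enumerated combinations per scaffold
#'   (seeded sampling without replacement above this).
#' @param rng_seed seed for combination sampling.
#' @return a `library_spec` list.
#' @export
library_spec <- function(scaffolds = default_scaffolds(),
                         substituents = c("", "F", "Cl", "Br", "C", "CC", "OC", "CCC", "CO"),
                         n_per_scaffold = 250L,
                         rng_seed = 42L) {
  stopifnot(nrow(scaffolds) >= 2, n_per_scaffold >= 1)
  structure(list(
    scaffolds = scaffolds,
    substituents = substituents,
    n_per_scaffold = as.integer(n_per_scaffold),
    rng_seed = as.integer(rng_seed)
  ), class = "library_spec")
}

.expand_template <- function(template, subs) {
  # sentinel keeps a trailing slot from being dropped by strsplit
  parts <- strsplit(paste0(template, "\u0001"), "(*)", fixed = TRUE)[[1]]
  parts[length(parts)] <- sub("\u0001$", "", parts[length(parts)])
  k <- length(parts) - 1L
  if (k == 0) return(template)
  wrapped <- ifelse(nzchar(subs), paste0("(", subs, ")"), "")
  grid <- do.call(expand.grid,
                  c(rep(list(seq_along(subs)), k),
                    list(KEEP.OUT.ATTRS = FALSE)))
  apply(grid, 1, function(ix) {
    out <- parts[1]
    for (j in seq_len(k)) out <- paste0(out, wrapped[ix[j]], parts[j + 1])
    out
  })
}

#' Generate a synthetic scaffold library
#'
#' Enumerates scaffold-template x substituent combinations (seeded sampling
#' without replacement above `n_per_scaffold` per scaffold), canonicalizes,
#' deduplicates (first scaffold wins) and sorts. Every generated molecule is
#' checked to pass standardization with verdict KEEP, and the library is
#' checked to contain at least two GFRG clusters under a shared
#' reduced-graph key (the precondition for negative sampling); violation of
#' either guarantee is an error at generation time.
#'
#' @param spec a [library_spec()].
#' @return data.frame with `canonical_smiles` and `scaffold` (template name
#'   of origin), sorted by `canonical_smiles`.
#' @export
generate_library <- function(spec = library_spec()) {
  set.seed(spec$rng_seed)
  raw <- list()
  for (i in seq_len(nrow(spec$scaffolds))) {
    subs <- spec$substituents
    if (!is.null(spec$scaffolds$allow_halogens) &&
        !spec$scaffolds$allow_halogens[i]) {
      subs <- setdiff(subs, c("F", "Cl", "Br", "I"))
    }
    combos <- .expand_template(spec$scaffolds$template[i], subs)
    if (length(combos) > spec$n_per_scaffold) {
      combos <- combos[sort(sample.int(length(combos), spec$n_per_scaffold))]
    }
    raw[[i]] <- data.frame(smiles = combos,
                           scaffold = spec$scaffolds$name[i],
                           stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, raw)
  cans <- canonical_smiles(raw$smiles)
  if (anyNA(cans)) {
    stop("library generation produced unparseable SMILES, e.g.: ",
         paste(utils::head(raw$smiles[is.na(cans)]), collapse = ", "))
  }
  lib <- data.frame(canonical_smiles = cans, scaffold = raw$scaffold,
                    stringsAsFactors = FALSE)
  lib <- lib[!duplicated(lib$canonical_smiles), , drop = FALSE]
  lib <- lib[order(lib$canonical_smiles), , drop = FALSE]
  rownames(lib) <- NULL
  std <- standardize_collection(lib$canonical_smiles)
  if (any(std$verdict != "KEEP")) {
    stop("library generation produced non-KEEP molecules, e.g.: ",
         paste(utils::head(lib$canonical_smiles[std$verdict != "KEEP"]),
               collapse = ", "))
  }
  # the standardized parent can differ from the raw canonical form
  # (neutralization is a no-op here, but keep the standardized string)
  lib$canonical_smiles <- std$canonical_smiles
  keys <- key_set(lib$canonical_smiles)
  per_rg <- tapply(keys$gf_key, keys$rg_key, function(x) length(unique(x)))
  if (!any(per_rg >= 2)) {
    stop("library spec cannot satisfy the two-cluster-per-reduced-graph guarantee")
  }
  lib
}

#' Activity table specification
#'
#' @param n_targets number of synthetic targets.
#' @param structures_per_target records per target.
#' @param label_rule `"scaffold_determined"` (pIC50 = scaffold base value +
#'   Gaussian noise), `"noisy_scaffold"` (same with additional noise) or
#'   `"random"` (scaffold-linked values randomly permuted across structures,
#'   destroying any structural signal).
#' @param noise_sd Gaussian noise standard deviation (pIC50 units).
#' @param rng_seed seed.
#' @return an `activity_spec` list.
#' @export
activity_spec <- function(n_targets = 3L,
                          structures_per_target = 200L,
                          label_rule = c("scaffold_determined",
                                         "noisy_scaffold", "random"),
                          noise_sd = 0.15,
                          rng_seed = 42L) {
  structure(list(
    n_targets = as.integer(n_targets),
    structures_per_target = as.integer(structures_per_target),
    label_rule = match.arg(label_rule),
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "activity_spec")
}

# scaffold families whose active members are compositionally distinct from
# the carbocyclic inactive pool (heteroatom content recoverable even by
# radius-0 fingerprints)
.active_pool <- c("pyridine", "thiophene", "oxazole")
.inactive_pool <- c("benzene", "cyclohexane", "cyclopentane", "decalin",
                    "biphenyl", "cyclohexanol", "cyclopentanol", "phenol")
.base_pic50 <- c(4.3, 5.3, 6.3) # inactive scaffold bases; active base:
.active_base <- 8.3

#' Generate a synthetic activity table
#'
#' Each target draws one "active" scaffold family (high base pIC50,
#' heteroatom-marked) and three inactive families (low bases); records are
#' molecules sampled from those families with pIC50 = base + noise, clamped
#' to [3, 11]. Under `label_rule = "random"` the pIC50 values are permuted
#' across the target's records, so labels carry no structural signal.
#'
#' @param spec an [activity_spec()].
#' @param library library data.frame from [generate_library()].
#' @return data.frame: `smiles`, `target_id`, `pic50`, `scaffold`.
#' @export
generate_activity <- function(spec = activity_spec(),
                              library = generate_library()) {
  stopifnot(nrow(library) > 0, "scaffold" %in% names(library))
  set.seed(spec$rng_seed)
  out <- vector("list", spec$n_targets)
  actives <- rep(.active_pool, length.out = spec$n_targets)
  for (t in seq_len(spec$n_targets)) {
    inact <- sample(intersect(.inactive_pool, unique(library$scaffold)), 3)
    fams <- c(inact, actives[t])
    bases <- c(.base_pic50, .active_base)
    per <- .split_count(spec$structures_per_target, 4L)
    recs <- list()
    for (f in seq_along(fams)) {
      pool <- library$canonical_smiles[library$scaffold == fams[f]]
      if (length(pool) < per[f]) {
        stop("scaffold family '", fams[f], "' has only ", length(pool),
             " members; reduce structures_per_target")
      }
      sm <- sample(pool, per[f])
      recs[[f]] <- data.frame(
        smiles = sm,
        target_id = paste0("T", t),
        pic50 = bases[f] + stats::rnorm(per[f], 0, spec$noise_sd),
        scaffold = fams[f],
        stringsAsFactors = FALSE
      )
    }
    out[[t]] <- do.call(rbind, recs)
  }
  # label-rule transformations come after all value generation, so the
  # random rule is a pure per-target permutation of the same value multiset
  for (t in seq_len(spec$n_targets)) {
    if (spec$label_rule == "noisy_scaffold") {
      out[[t]]$pic50 <- out[[t]]$pic50 + stats::rnorm(nrow(out[[t]]), 0, 1.0)
    }
    if (spec$label_rule == "random") {
      out[[t]]$pic50 <- sample(out[[t]]$pic50)
    }
    out[[t]]$pic50 <- pmin(pmax(out[[t]]$pic50, 3), 11)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.split_count <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}
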