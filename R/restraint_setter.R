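# ---------------------------------------------------------------------------
# RestraintSetter: decide which mapped heavy-atom pairs get cross-topology
# distance restraints, from a hierarchical atom-equivalence criterion plus a
# ring-substituent strictness level.
# ---------------------------------------------------------------------------

#' Restraint equivalence configuration
#'
#' @param atom_compare_method one of `"element"`, `"hybridization"`,
#'   `"aromaticity"`, `"heavyatom"`: the atom-level equivalence criterion.
#' @param surround_strictness one of `"permissive"`, `"less_strict"`,
#'   `"strict"`: how ring substituent positions are compared.
#' @return object of class `equivalence_config`.
#' @details The compact string form uses the suffix convention
#'   `_p` / `_ls` / `_s`, e.g. `"heavyatom_p"` (the default configuration:
#'   all heavy atoms equivalent, only ring atoms compared).
#' @seealso [parse_equivalence_config()], [set_restraints()]
#' @export
equivalence_config <- function(atom_compare_method = "heavyatom",
                               surround_strictness = "permissive") {
  atom_compare_method <- match.arg(atom_compare_method,
    c("element", "hybridization", "aromaticity", "heavyatom"))
  surround_strictness <- match.arg(surround_strictness,
    c("permissive", "less_strict", "strict"))
  structure(list(atom_compare_method = atom_compare_method,
                 surround_strictness = surround_strictness),
            class = "equivalence_config")
}

#' @export
print.equivalence_config <- function(x, ...) {
  cat(sprintf("<equivalence_config> %s\n", format_equivalence_config(x)))
  invisible(x)
}

#' Format an equivalence configuration as its suffix string
#' @param config an [equivalence_config()].
#' @return e.g. `"heavyatom_p"`, `"element_ls"`, `"aromaticity_s"`.
#' @export
format_equivalence_config <- function(config) {
  suf <- c(permissive = "p", less_strict = "ls", strict = "s")
  paste0(config$atom_compare_method, "_", suf[[config$surround_strictness]])
}

#' Parse a suffix-form configuration string
#' @param s e.g. `"heavyatom_p"`, `"element_ls"`.
#' @return an [equivalence_config()].
#' @export
parse_equivalence_config <- function(s) {
  m <- regmatches(s, regexec("^(element|hybridization|aromaticity|heavyatom)_(p|ls|s)$", s))[[1]]
  if (length(m) != 3L) stop("unrecognised config string: ", s)
  lev <- c(p = "permissive", ls = "less_strict", s = "strict")
  equivalence_config(m[2], lev[[m[3]]])
}

#' Atom-level equivalence test
#'
#' @param molA,molB [molecule()] records.
#' @param ai,bi 1-based heavy-atom indices into A and B.
#' @param method atom comparison criterion: `"element"` (same element
#'   symbol), `"hybridization"` (same sp label), `"aromaticity"` (same
#'   aromatic flag), `"heavyatom"` (any two heavy atoms are equivalent).
#' @return logical.
#' @export
atoms_equivalent <- function(molA, ai, molB, bi, method = "heavyatom") {
  if (!molA$atoms$heavy[ai] || !molB$atoms$heavy[bi])
    stop("atoms_equivalent is defined for heavy atoms only")
  switch(method,
    element       = molA$atoms$element[ai] == molB$atoms$element[bi],
    hybridization = molA$atoms$hybridization[ai] == molB$atoms$hybridization[bi],
    aromaticity   = molA$atoms$aromatic[ai] == molB$atoms$aromatic[bi],
    heavyatom     = TRUE,
    stop("unknown atom_compare_method: ", method))
}

#' Ring-to-ring correspondences implied by an atom mapping
#'
#' Ring `rA` of molecule A corresponds to ring `rB` of B when strictly more
#' than half of the smaller ring's atoms are mapped between them. Each ring
#' enters at most one correspondence (best overlap wins; ties to the
#' first-listed ring).
#'
#' @param mapping an [atom_mapping()].
#' @param molA,molB [molecule()] records with perceived rings.
#' @return data.frame with columns `ringA`, `ringB` (ring list indices).
#' @export
ring_correspondences <- function(mapping, molA, molB) {
  ringsA <- molA$rings$rings; ringsB <- molB$rings$rings
  out <- data.frame(ringA = integer(), ringB = integer())
  if (!length(ringsA) || !length(ringsB) || !nrow(mapping$pairs)) return(out)
  p <- mapping$pairs
  b_of <- structure(p$b, names = p$a)
  cand <- expand.grid(ringA = seq_along(ringsA), ringB = seq_along(ringsB))
  cand$overlap <- mapply(function(ra, rb) {
    mapped <- b_of[as.character(ringsA[[ra]])]
    sum(!is.na(mapped) & mapped %in% ringsB[[rb]])
  }, cand$ringA, cand$ringB)
  cand$smaller <- pmin(lengths(ringsA)[cand$ringA], lengths(ringsB)[cand$ringB])
  cand <- cand[cand$overlap * 2L > cand$smaller, , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$ringA, cand$ringB), , drop = FALSE]
  usedA <- logical(length(ringsA)); usedB <- logical(length(ringsB))
  for (k in seq_len(nrow(cand))) {
    ra <- cand$ringA[k]; rb <- cand$ringB[k]
    if (usedA[ra] || usedB[rb]) next
    usedA[ra] <- TRUE; usedB[rb] <- TRUE
    out <- rbind(out, data.frame(ringA = ra, ringB = rb))
  }
  rownames(out) <- NULL
  out
}

# first heavy atom bonded to ring atom `idx` outside its ring system
ring_substituents <- function(mol, idx) {
  bd <- mol$bonds
  nbrs <- c(bd$j[bd$i == idx], bd$i[bd$j == idx])
  nbrs <- nbrs[mol$atoms$heavy[nbrs] & !mol$atoms$in_ring[nbrs]]
  sort(nbrs)
}

#' Ring-substituent equivalence at a mapped ring position
#'
#' Compares the R-group situation at two corresponding ring positions.
#' `"permissive"` compares ring atoms only (always true here);
#' `"less_strict"` requires both positions to agree on the *presence* of a
#' heavy-atom substituent, element ignored; `"strict"` additionally requires
#' the first atom of each substituent to match by element. Branched
#' substituents are compared by their first atom only.
#'
#' @param molA,molB [molecule()] records.
#' @param ai,bi mapped ring-atom indices in corresponding rings.
#' @param strictness `"permissive"`, `"less_strict"` or `"strict"`.
#' @return logical.
#' @export
substituents_equivalent <- function(molA, ai, molB, bi,
                                    strictness = "permissive") {
  if (strictness == "permissive") return(TRUE)
  subA <- ring_substituents(molA, ai)
  subB <- ring_substituents(molB, bi)
  if (length(subA) != length(subB)) return(FALSE)
  if (strictness == "less_strict") return(TRUE)
  # strict: element of the first substituent atom(s), order-insensitive
  identical(sort(molA$atoms$element[subA]), sort(molB$atoms$element[subB]))
}

#' Generate cross-topology distance restraints (RestraintSetter)
#'
#' For each mapped pair of ring atoms lying in corresponding rings, a
#' restraint is emitted iff the atoms are equivalent under
#' `atom_compare_method` *and* their substituent positions are equivalent
#' under `surround_strictness`. Mapped acyclic heavy-atom pairs use the
#' atom-level criterion alone. Unmapped atoms are never restrained. Every
#' emitted restraint carries the default force constant 0.5 kcal/mol/A^2,
#' activated when the pair distance exceeds 0.1 A.
#'
#' @param molA,molB [molecule()] records (rings perceived).
#' @param mapping an [atom_mapping()] that has passed the sanity filters.
#' @param config an [equivalence_config()] or suffix string
#'   (default `"heavyatom_p"`).
#' @param force_constant restraint force constant, kcal/mol/A^2.
#' @param activation activation distance, Angstrom.
#' @return object of class `restraint_set`: data.frame `pairs` (`a`, `b`,
#'   `k`, `activation`, `provenance` in {"ring match", "acyclic match"}),
#'   the `config` used, and `excluded` (mapped pairs dropped, with the rule
#'   that dropped each).
#' @export
set_restraints <- function(molA, molB, mapping,
                           config = equivalence_config(),
                           force_constant = 0.5, activation = 0.1) {
  if (is.character(config)) config <- parse_equivalence_config(config)
  stopifnot(force_constant > 0)
  p <- mapping$pairs
  if (!nrow(p)) {
    warning("empty mapping: empty restraint set")
    return(restraint_set(NULL, config))
  }
  rc <- ring_correspondences(mapping, molA, molB)
  ring_pair_of <- function(ai, bi) {
    for (k in seq_len(nrow(rc))) {
      if (ai %in% molA$rings$rings[[rc$ringA[k]]] &&
          bi %in% molB$rings$rings[[rc$ringB[k]]]) return(k)
    }
    NA_integer_
  }
  keep <- logical(nrow(p)); prov <- character(nrow(p)); rule <- character(nrow(p))
  for (k in seq_len(nrow(p))) {
    ai <- p$a[k]; bi <- p$b[k]
    if (!molA$atoms$heavy[ai] || !molB$atoms$heavy[bi]) {
      rule[k] <- "hydrogen"; next
    }
    in_corr_ring <- !is.na(ring_pair_of(ai, bi))
    if (in_corr_ring) {
      if (!atoms_equivalent(molA, ai, molB, bi, config$atom_compare_method)) {
        rule[k] <- paste0("atom_compare:", config$atom_compare_method); next
      }
      if (!substituents_equivalent(molA, ai, molB, bi, config$surround_strictness)) {
        rule[k] <- paste0("surround:", config$surround_strictness); next
      }
      keep[k] <- TRUE; prov[k] <- "ring match"
    } else {
      if (!atoms_equivalent(molA, ai, molB, bi, config$atom_compare_method)) {
        rule[k] <- paste0("atom_compare:", config$atom_compare_method); next
      }
      keep[k] <- TRUE; prov[k] <- "acyclic match"
    }
  }
  pairs <- data.frame(a = p$a[keep], b = p$b[keep],
                      k = force_constant, activation = activation,
                      provenance = prov[keep])
  excluded <- data.frame(a = p$a[!keep], b = p$b[!keep], rule = rule[!keep])
  restraint_set(pairs, config, excluded)
}

#' Construct a restraint set
#' @param pairs data.frame (`a`, `b`, `k`, `activation`, `provenance`) or NULL.
#' @param config the [equivalence_config()] used.
#' @param excluded data.frame of mapped-but-excluded pairs with the rule.
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(pairs, config = equivalence_config(),
                          excluded = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    pairs <- data.frame(a = integer(), b = integer(), k = numeric(),
                        activation = numeric(), provenance = character())
  if (anyDuplicated(pairs[, c("a", "b")])) stop("duplicate restraint pair")
  if (is.null(excluded))
    excluded <- data.frame(a = integer(), b = integer(), rule = character())
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, config = config, excluded = excluded),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d restraint(s) [%s], %d mapped pair(s) excluded\n",
              nrow(x$pairs), format_equivalence_config(x$config),
              nrow(x$excluded)))
  invisible(x)
}

#' Write a restraint set as TSV (0-based indices)
#'
#' Emits `indexA  indexB  k  activation  provenance` plus a commented run
#' log listing every mapped pair excluded and the rule that excluded it.
#' @param rs a [restraint_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config: %s", format_equivalence_config(rs$config)), con)
  for (k in seq_len(nrow(rs$excluded)))
    writeLines(sprintf("# excluded: %d %d (%s)", rs$excluded$a[k] - 1L,
                       rs$excluded$b[k] - 1L, rs$excluded$rule[k]), con)
  writeLines("indexA\tindexB\tk\tactivation\tprovenance", con)
  p <- rs$pairs
  if (nrow(p))
    writeLines(sprintf("%d\t%d\t%.6g\t%.6g\t%s", p$a - 1L, p$b - 1L,
                       p$k, p$activation, p$provenance), con)
  invisible(path)
}

#' Read a restraint set TSV written by [write_restraints()]
#' @param path input path.
#' @return a [restraint_set()] (config restored from the header).
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cfg <- equivalence_config()
  hdr <- grep("^# config:", lines, value = TRUE)
  if (length(hdr)) cfg <- parse_equivalence_config(trimws(sub("^# config:", "", hdr[1])))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body)) & !grepl("^indexA", body)]
  if (!length(body)) return(restraint_set(NULL, cfg))
  f <- do.call(rbind, strsplit(body, "\t"))
  restraint_set(data.frame(a = as.integer(f[, 1]) + 1L,
                           b = as.integer(f[, 2]) + 1L,
                           k = as.numeric(f[, 3]),
                           activation = as.numeric(f[, 4]),
                           provenance = f[, 5]), cfg)
}
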