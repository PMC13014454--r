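# ---------------------------------------------------------------------------
# Molecular data model
# ---------------------------------------------------------------------------

#' Construct a molecule record
#'
#' A small molecule represented as an atom/bond graph with 3D coordinates.
#' Atom indices are 1-based and contiguous; serialized interchange formats
#' (mapping and restraint TSVs) use 0-based indices, converted at the I/O
#' boundary. Ring membership, aromaticity and hybridization are (re)perceived
#' on construction so downstream equivalence checks always see consistent
#' annotations.
#'
#' @param name text identifier.
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge, e), `x`, `y`, `z` (Angstrom).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic). May have zero rows.
#' @param perceive logical; run ring/aromaticity/hybridization perception.
#' @return An object of class `molecule` with elements `name`, `atoms`
#'   (adds `aromatic`, `in_ring`, `hybridization`, `heavy` columns),
#'   `bonds` (adds `aromatic`), and `rings` (a [ring_system()]).
#' @seealso [read_sdf()], [perceive_rings()], [net_formal_charge()]
#' @export
molecule <- function(name, atoms, bonds, perceive = TRUE) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  need <- c("element", "charge", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1L) stop("molecule must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atomic coordinates")
  if (nrow(bonds) > 0L) {
    if (!all(c("i", "j", "order") %in% names(bonds)))
      stop("bonds needs columns i, j, order")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references a non-existent atom")
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$heavy <- atoms$element != "H"
  mol <- structure(
    list(name = as.character(name), atoms = atoms,
         bonds = bonds, rings = NULL),
    class = "molecule")
  if (perceive) mol <- perceive_all(mol)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%d heavy), %d bonds, %d ring(s), net charge %+d\n",
              x$name, nrow(x$atoms), sum(x$atoms$heavy), nrow(x$bonds),
              length(x$rings$rings), net_formal_charge(x)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @param heavy_only count heavy (non-hydrogen) atoms only.
#' @return integer count.
#' @export
n_atoms <- function(mol, heavy_only = FALSE) {
  if (heavy_only) sum(mol$atoms$heavy) else nrow(mol$atoms)
}

#' Net formal charge of a molecule
#'
#' Sum of per-atom formal charges; used by the same-charge transformation
#' gate ([validate_same_charge()]).
#' @param mol a [molecule()].
#' @return integer net charge in elementary charge units.
#' @export
net_formal_charge <- function(mol) {
  as.integer(sum(mol$atoms$charge))
}

#' Atomic coordinates as a matrix
#' @param mol a [molecule()].
#' @param heavy_only restrict to heavy atoms.
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(mol, heavy_only = FALSE) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  if (heavy_only) m[mol$atoms$heavy, , drop = FALSE] else m
}

# ---------------------------------------------------------------------------
# Ring perception: smallest set of smallest rings (SSSR)
# ---------------------------------------------------------------------------

#' Construct a ring system
#' @param rings list of integer vectors (1-based atom indices, one per ring).
#' @return object of class `ring_system` with `rings` and `sizes`.
#' @export
ring_system <- function(rings) {
  rings <- lapply(rings, function(r) sort(unique(as.integer(r))))
  sizes <- vapply(rings, length, integer(1))
  if (length(sizes) && any(sizes < 3L)) stop("ring size must be >= 3")
  structure(list(rings = rings, sizes = sizes), class = "ring_system")
}

#' @export
print.ring_system <- function(x, ...) {
  cat(sprintf("<ring_system> %d ring(s)%s\n", length(x$rings),
              if (length(x$sizes))
                paste0(", sizes {", paste(x$sizes, collapse = ", "), "}")
              else ""))
  invisible(x)
}

# adjacency list over all atoms (by bond table)
adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Shortest cycle through edge (u,v): BFS from u to v with edge (u,v) removed.
shortest_cycle_through_edge <- function(adj, u, v) {
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (cur == u && nb == v) next  # the removed edge
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        if (nb == v) {
          path <- v
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)  # u ... v; closing edge (v,u) completes the cycle
        }
        queue <- c(queue, nb)
      }
    }
  }
  NULL
}

#' Perceive the smallest set of smallest rings
#'
#' Computes an SSSR by collecting, for every bond, the smallest cycle
#' containing it, then greedily keeping rings in order of size until the
#' cyclomatic number (bonds - atoms + components) of candidate rings is
#' reached, requiring each kept ring to contribute an edge not covered by
#' smaller rings.
#'
#' @param mol a [molecule()].
#' @return a [ring_system()]. Acyclic molecules give an empty ring list.
#' @export
perceive_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(ring_system(list()))
  adj <- adjacency(mol)
  n <- nrow(mol$atoms)
  # number of independent cycles
  comp <- n_components(adj)
  n_rings <- nb - n + comp
  if (n_rings <= 0L) return(ring_system(list()))
  cand <- list()
  for (k in seq_len(nb)) {
    cyc <- shortest_cycle_through_edge(adj, mol$bonds$i[k], mol$bonds$j[k])
    if (!is.null(cyc)) cand[[length(cand) + 1L]] <- cyc
  }
  if (!length(cand)) return(ring_system(list()))
  sizes <- vapply(cand, length, integer(1))
  cand <- cand[order(sizes, vapply(cand, function(r) paste(sort(r), collapse = ","), ""))]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  covered <- character(0)
  kept <- list()
  for (r in cand) {
    if (length(kept) >= n_rings) break
    ring_atoms <- sort(unique(r))
    if (any(vapply(kept, function(x) identical(x, ring_atoms), logical(1)))) next
    eks <- edge_key(r, c(r[-1], r[1]))
    if (all(eks %in% covered)) next
    covered <- union(covered, eks)
    kept[[length(kept) + 1L]] <- ring_atoms
  }
  ring_system(kept)
}

n_components <- function(adj) {
  n <- length(adj)
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (x in adj[[cur]]) if (!seen[x]) { seen[x] <- TRUE; queue <- c(queue, x) }
    }
  }
  comp
}

# ---------------------------------------------------------------------------
# Aromaticity and hybridization perception
# ---------------------------------------------------------------------------

# Perception model (fixed across a run; see the methods vignette):
#  - a ring is aromatic iff all its bonds have SDF order 4, OR its size is
#    5 or 6 and every ring atom is pi-capable (has a double/triple/order-4
#    bond, or is N/O/S whose lone pair can enter the ring pi system);
#  - hybridization from bond orders: any triple or >= 2 doubles -> sp;
#    any double or aromatic flag -> sp2; otherwise sp3.
perceive_all <- function(mol) {
  mol$rings <- perceive_rings(mol)
  at <- mol$atoms
  bd <- mol$bonds
  n <- nrow(at)
  at$in_ring <- rep(FALSE, n)
  for (r in mol$rings$rings) at$in_ring[r] <- TRUE

  has_mult <- rep(FALSE, n)  # participates in a double/triple/order-4 bond
  if (nrow(bd)) {
    mult <- bd$order >= 2L
    has_mult[unique(c(bd$i[mult], bd$j[mult]))] <- TRUE
  }
  pi_capable <- has_mult | at$element %in% c("N", "O", "S")

  aromatic_ring <- logical(length(mol$rings$rings))
  bond_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bkey <- if (nrow(bd)) bond_id(bd$i, bd$j) else character(0)
  for (ri in seq_along(mol$rings$rings)) {
    r <- mol$rings$rings[[ri]]
    ring_bonds <- which(bkey %in% bond_id(rep(r, each = length(r)),
                                          rep(r, times = length(r))) &
                          bd$i %in% r & bd$j %in% r)
    all4 <- length(ring_bonds) > 0 && all(bd$order[ring_bonds] == 4L)
    aromatic_ring[ri] <- all4 ||
      (length(r) %in% c(5L, 6L) && all(pi_capable[r]))
  }

  at$aromatic <- rep(FALSE, n)
  bd$aromatic <- if (nrow(bd)) bd$order == 4L else logical(0)
  for (ri in which(aromatic_ring)) {
    r <- mol$rings$rings[[ri]]
    at$aromatic[r] <- TRUE
    in_r <- bd$i %in% r & bd$j %in% r
    bd$aromatic[in_r] <- TRUE
  }

  hyb <- rep("sp3", n)
  if (nrow(bd)) {
    for (a in seq_len(n)) {
      rows <- bd$i == a | bd$j == a
      if (!any(rows)) next
      o <- bd$order[rows]
      arom <- any(bd$aromatic[rows])
      if (any(o == 3L) || sum(o == 2L) >= 2L) hyb[a] <- "sp"
      else if (any(o == 2L) || any(o == 4L) || arom) hyb[a] <- "sp2"
    }
  }
  # atoms flagged aromatic by ring perception are planar
  hyb[at$aromatic & hyb == "sp3"] <- "sp2"
  at$hybridization <- hyb
  mol$atoms <- at
  mol$bonds <- bd
  mol
}

#' Smallest ring containing an atom
#' @param mol a [molecule()].
#' @param idx 1-based atom index.
#' @return integer size of the smallest ring the atom belongs to, or
#'   `NA_integer_` if the atom is acyclic.
#' @export
smallest_ring_size <- function(mol, idx) {
  sz <- mol$rings$sizes[vapply(mol$rings$rings, function(r) idx %in% r, logical(1))]
  if (length(sz)) min(sz) else NA_integer_
}

# ---------------------------------------------------------------------------
# SDF I/O
# ---------------------------------------------------------------------------

#' Read molecules from an SDF file
#'
#' Parses V2000 and V3000 connection tables, taking formal charges from
#' `M  CHG` lines (V2000) or `CHG=` atom attributes (V3000); the legacy
#' per-atom charge-code column is honoured when no `M  CHG` line is present.
#' Entry order in the file is preserved. Records flagged 2D (dimension code
#' `2D` and all z = 0) are returned with a warning since distance-based
#' mapping needs 3D poses.
#'
#' @param path SDF file path.
#' @return list of [molecule()] records.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # split entries on $$$$
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  entry_no <- 0L
  for (b in seq_along(starts)) {
    chunk <- lines[starts[b]:ends[b]]
    chunk <- chunk[cumsum(grepl("^\\$\\$\\$\\$", chunk)) == 0L]
    if (!length(chunk) || all(!nzchar(trimws(chunk)))) next
    entry_no <- entry_no + 1L
    mol <- tryCatch(parse_sdf_entry(chunk),
                    error = function(e)
                      stop(sprintf("SDF entry %d: %s", entry_no, conditionMessage(e)),
                           call. = FALSE))
    out[[entry_no]] <- mol
  }
  out
}

parse_sdf_entry <- function(chunk) {
  if (length(chunk) < 4L) stop("truncated header block")
  name <- trimws(chunk[1])
  if (!nzchar(name)) name <- "unnamed"
  counts <- chunk[4]
  v3000 <- grepl("V3000", counts)
  if (v3000) parse_sdf_v3000(chunk, name) else parse_sdf_v2000(chunk, name)
}

parse_sdf_v2000 <- function(chunk, name) {
  counts <- chunk[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) stop("malformed counts line")
  if (length(chunk) < 4L + natoms + nbonds) stop("truncated atom/bond block")
  dim2d <- grepl("2D", chunk[2], fixed = TRUE)
  at <- chunk[4L + seq_len(natoms)]
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  el <- trimws(substr(at, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("malformed atom line")
  ccode <- suppressWarnings(as.integer(substr(at, 37, 39)))
  # legacy charge codes: 1->+3 2->+2 3->+1 4->radical 5->-1 6->-2 7->-3
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- ifelse(!is.na(ccode) & ccode %in% names2int(legacy),
                   legacy[as.character(ccode)], 0L)
  charge[is.na(charge)] <- 0L
  bl <- chunk[4L + natoms + seq_len(nbonds)]
  bi <- as.integer(substr(bl, 1, 3))
  bj <- as.integer(substr(bl, 4, 6))
  bo <- as.integer(substr(bl, 7, 9))
  if (any(is.na(bi) | is.na(bj) | is.na(bo))) stop("malformed bond line")
  chg_lines <- grep("^M  CHG", chunk, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, natoms)  # M CHG supersedes the legacy column entirely
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", cl)), "\\s+")[[1]])
      if (length(f) %% 2L != 0L) stop("malformed M  CHG line")
      idx <- f[seq(1, length(f), 2)]
      val <- f[seq(2, length(f), 2)]
      charge[idx] <- val
    }
  }
  if (dim2d && all(z == 0)) warning(sprintf("entry '%s' has 2D coordinates", name))
  molecule(name,
           data.frame(element = el, charge = as.integer(charge),
                      x = x, y = y, z = z),
           data.frame(i = bi, j = bj, order = bo))
}

names2int <- function(v) names(v)

parse_sdf_v3000 <- function(chunk, name) {
  grab <- function(tag) {
    i0 <- grep(paste0("BEGIN ", tag), chunk)
    i1 <- grep(paste0("END ", tag), chunk)
    if (!length(i0) || !length(i1)) return(character(0))
    if (i1[1] - i0[1] < 2L) return(character(0))
    chunk[(i0[1] + 1L):(i1[1] - 1L)]
  }
  al <- grab("ATOM")
  if (!length(al)) stop("V3000 entry without ATOM block")
  parse_atom <- function(line) {
    toks <- strsplit(trimws(sub("^M  V30\\s*", "", line)), "\\s+")[[1]]
    chg <- 0L
    kv <- grep("^CHG=", toks, value = TRUE)
    if (length(kv)) chg <- as.integer(sub("^CHG=", "", kv[1]))
    list(el = toks[2], x = as.numeric(toks[3]), y = as.numeric(toks[4]),
         z = as.numeric(toks[5]), chg = chg)
  }
  pa <- lapply(al, parse_atom)
  bl <- grab("BOND")
  pb <- lapply(bl, function(line) {
    toks <- strsplit(trimws(sub("^M  V30\\s*", "", line)), "\\s+")[[1]]
    as.integer(toks[2:4])  # order, atom1, atom2
  })
  atoms <- data.frame(
    element = vapply(pa, `[[`, "", "el"),
    charge = vapply(pa, `[[`, 0L, "chg"),
    x = vapply(pa, `[[`, 0, "x"),
    y = vapply(pa, `[[`, 0, "y"),
    z = vapply(pa, `[[`, 0, "z"))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("malformed V3000 atom line")
  bonds <- if (length(pb))
    data.frame(i = vapply(pb, `[`, 0L, 2),
               j = vapply(pb, `[`, 0L, 3),
               order = vapply(pb, `[`, 0L, 1))
  else data.frame(i = integer(), j = integer(), order = integer())
  molecule(name, atoms, bonds)
}

#' Write molecules to an SDF (V2000) file
#'
#' Formal charges are emitted as `M  CHG` lines. Round-trips atom count,
#' elements, charges and coordinates (to the 4-decimal SDF precision).
#'
#' @param mols a [molecule()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    lines <- c(mol$name, "  rbfekit          3D", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              at$x, at$y, at$z, at$element))
    if (nrow(bd))
      lines <- c(lines, sprintf("%3d%3d%3d  0", bd$i, bd$j, bd$order))
    chg <- which(at$charge != 0L)
    for (s in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(s)),
                               paste(sprintf("%4d%4d", s, at$charge[s]),
                                     collapse = "")))
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# PDB I/O
# ---------------------------------------------------------------------------

#' Read a protein structure from PDB
#'
#' Fixed-column parsing via bio3d; the element is taken from the element
#' column when present, otherwise inferred from the atom name in residue
#' context (so `CA` inside an amino-acid residue is carbon, not calcium).
#' Only the first model and the first alternate location are kept (noted
#' by message when others are dropped). Waters are recognised by residue
#' name (HOH/WAT/SPC/T3P).
#'
#' @param path PDB file path.
#' @return object of class `protein`: data.frame `atoms` with columns
#'   `element`, `name`, `resid`, `resno`, `chain`, `x`, `y`, `z`, `heavy`,
#'   `is_water`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no ATOM/HETATM records in ", path)
  if (any(!is.na(a$alt) & a$alt != "" & a$alt != "A")) {
    a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
    message("read_pdb: kept first alternate location only")
  }
  el <- a$elesy
  missing_el <- is.na(el) | !nzchar(trimws(el))
  if (any(missing_el))
    el[missing_el] <- bio3d::atom2ele(a$elety[missing_el])
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  atoms <- data.frame(
    element = el, name = a$elety, resid = a$resid, resno = a$resno,
    chain = a$chain, x = a$x, y = a$y, z = a$z,
    heavy = el != "H",
    is_water = a$resid %in% c("HOH", "WAT", "SPC", "T3P"),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, source = path), class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  cat(sprintf("<protein> %d atoms (%d heavy, %d water) from %s\n",
              nrow(x$atoms), sum(x$atoms$heavy), sum(x$atoms$is_water),
              x$source %||% "memory"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write atoms to a PDB file
#'
#' Fixed-column ATOM/HETATM writer used for droplet output. `record` selects
#' ATOM vs HETATM per row (waters default to HETATM).
#'
#' @param atoms data.frame with columns `element`, `name`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`.
#' @param path output path.
#' @param record optional character vector "ATOM"/"HETATM" per row.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, record = NULL) {
  n <- nrow(atoms)
  if (is.null(record))
    record <- ifelse(atoms$resid %in% c("HOH", "WAT", "SPC", "T3P"),
                     "HETATM", "ATOM")
  chain <- atoms$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  lines <- sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   record, seq_len(n) %% 100000L,
                   substr(atoms$name, 1, 3),
                   substr(atoms$resid, 1, 3), substr(chain, 1, 1),
                   atoms$resno %% 10000L,
                   atoms$x, atoms$y, atoms$z, substr(atoms$element, 1, 2))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
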