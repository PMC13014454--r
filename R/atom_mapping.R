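# ---------------------------------------------------------------------------
# Cartesian-overlap atom mapping between two aligned ligands
# ---------------------------------------------------------------------------

#' Construct an atom mapping
#'
#' A one-to-one partial correspondence between heavy atoms of two ligands.
#' Indices are 1-based internally; the TSV interchange format
#' ([write_mapping()]) is 0-based.
#'
#' @param pairs data.frame with integer columns `a`, `b` (may be empty).
#' @param source provenance tag, `"distance"` or `"manual"`.
#' @return object of class `atom_mapping`.
#' @export
atom_mapping <- function(pairs, source = "distance") {
  if (is.null(pairs) || nrow(pairs) == 0L)
    pairs <- data.frame(a = integer(), b = integer())
  pairs <- data.frame(a = as.integer(pairs$a), b = as.integer(pairs$b))
  if (anyDuplicated(pairs$a) || anyDuplicated(pairs$b))
    stop("mapping must be one-to-one")
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, source = source), class = "atom_mapping")
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping> %d pair(s), source: %s\n", nrow(x$pairs), x$source))
  invisible(x)
}

#' Number of mapped pairs
#' @param mapping an [atom_mapping()].
#' @return integer.
#' @export
n_pairs <- function(mapping) nrow(mapping$pairs)

# ---------------------------------------------------------------------------
# Hungarian algorithm (minimum-cost assignment, square matrix, potentials)
# ---------------------------------------------------------------------------

# Returns assignment: integer vector, row i -> column assign[i] (NA if the
# matrix was padded). Costs may be Inf for forbidden pairs provided a finite
# perfect matching exists on the padded matrix; callers pad with a large
# finite cost instead of Inf.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  # potentials u (rows), v (cols); p[j] = row matched to column j (0 = none)
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(m + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1L:(m + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in 2L:(m + 1L)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Map atoms between two ligands by Cartesian overlap
#'
#' Minimum-total-distance one-to-one assignment over heavy-atom pairs whose
#' Cartesian distance does not exceed `cutoff`. Element identity is not
#' required here: the sanity filters and the restraint equivalence criteria
#' decide chemistry later. Deterministic; assignment ties are broken toward
#' the lowest (index in A, index in B).
#'
#' @param molA,molB [molecule()] records with 3D coordinates, pre-aligned.
#' @param cutoff maximum pair distance in Angstrom (default 0.95, the
#'   Cartesian-mapper convention).
#' @return an [atom_mapping()] with source `"distance"`. If no heavy-atom
#'   pair lies within the cutoff an empty mapping is returned with a warning.
#' @export
map_by_distance <- function(molA, molB, cutoff = 0.95) {
  stopifnot(cutoff > 0)
  ia <- which(molA$atoms$heavy)
  ib <- which(molB$atoms$heavy)
  if (!length(ia) || !length(ib)) {
    warning("no heavy atoms to map")
    return(atom_mapping(NULL))
  }
  ca <- coords(molA)[ia, , drop = FALSE]
  cb <- coords(molB)[ib, , drop = FALSE]
  d <- sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb))
  d[!is.finite(d) | d < 0] <- 0
  if (!any(d <= cutoff)) {
    warning("no atom pair within cutoff; empty mapping")
    return(atom_mapping(NULL))
  }
  # forbidden pairs get a large finite cost; tiny index-based epsilon breaks
  # cost ties deterministically toward low (a, b)
  big <- max(cutoff * 1e6, 1e6)
  cost <- d
  cost[d > cutoff] <- big
  nA <- length(ia); nB <- length(ib)
  eps <- 1e-9 * (outer(seq_len(nA), seq_len(nB), function(i, j) i * (nB + 1) + j))
  transposed <- nA > nB
  if (transposed) {
    assign <- solve_assignment(t(cost + eps))
    pairs <- data.frame(a = ia[assign[!is.na(assign)]],
                        b = ib[which(!is.na(assign))],
                        d = d[cbind(assign[!is.na(assign)], which(!is.na(assign)))])
  } else {
    assign <- solve_assignment(cost + eps)
    pairs <- data.frame(a = ia[which(!is.na(assign))],
                        b = ib[assign[!is.na(assign)]],
                        d = d[cbind(which(!is.na(assign)), assign[!is.na(assign)])])
  }
  pairs <- pairs[pairs$d <= cutoff, c("a", "b"), drop = FALSE]
  if (!nrow(pairs)) {
    warning("no atom pair within cutoff; empty mapping")
    return(atom_mapping(NULL))
  }
  atom_mapping(pairs)
}

# ---------------------------------------------------------------------------
# Mapping sanity filters
# ---------------------------------------------------------------------------

#' Drop mapped pairs that would break a ring
#'
#' Removes every pair in which exactly one partner is a ring atom, so a ring
#' atom is never transformed into a chain atom. Idempotent.
#'
#' @param mapping an [atom_mapping()].
#' @param molA,molB the mapped [molecule()] records (ring perception done).
#' @return filtered [atom_mapping()].
#' @export
filter_ringbreak <- function(mapping, molA, molB) {
  p <- mapping$pairs
  if (!nrow(p)) return(mapping)
  keep <- molA$atoms$in_ring[p$a] == molB$atoms$in_ring[p$b]
  atom_mapping(p[keep, , drop = FALSE], mapping$source)
}

#' Drop mapped pairs whose ring sizes differ
#'
#' For pairs where both atoms are in rings, compares the size of each atom's
#' smallest containing ring and removes the pair on mismatch (a cyclopentyl
#' atom is never matched to a phenyl atom). Chain-chain pairs are untouched.
#' Idempotent.
#'
#' @inheritParams filter_ringbreak
#' @return filtered [atom_mapping()].
#' @export
filter_ringsize <- function(mapping, molA, molB) {
  p <- mapping$pairs
  if (!nrow(p)) return(mapping)
  keep <- vapply(seq_len(nrow(p)), function(k) {
    sa <- smallest_ring_size(molA, p$a[k])
    sb <- smallest_ring_size(molB, p$b[k])
    if (is.na(sa) && is.na(sb)) return(TRUE)   # chain-chain
    if (is.na(sa) || is.na(sb)) return(TRUE)   # ringbreak filter's job
    sa == sb
  }, logical(1))
  atom_mapping(p[keep, , drop = FALSE], mapping$source)
}

#' Keep ring mappings only when whole rings are mapped
#'
#' A ring atom's pair survives only if every atom of every ring it belongs
#' to (on both sides) is mapped to a ring partner; partially mapped rings
#' are dropped atom-by-atom. Acyclic pairs are untouched. Idempotent.
#'
#' @inheritParams filter_ringbreak
#' @return filtered [atom_mapping()].
#' @export
filter_whole_rings_only <- function(mapping, molA, molB) {
  p <- mapping$pairs
  if (!nrow(p)) return(mapping)
  mappedA <- p$a[molB$atoms$in_ring[p$b]]  # A atoms mapped to a ring partner
  mappedB <- p$b[molA$atoms$in_ring[p$a]]
  ring_ok <- function(rings, mapped) {
    vapply(rings, function(r) all(r %in% mapped), logical(1))
  }
  okA <- ring_ok(molA$rings$rings, intersect(p$a, mappedA))
  okB <- ring_ok(molB$rings$rings, intersect(p$b, mappedB))
  bad_a <- unlist(molA$rings$rings[!okA])
  bad_b <- unlist(molB$rings$rings[!okB])
  keep <- !(p$a %in% bad_a & molA$atoms$in_ring[p$a]) &
          !(p$b %in% bad_b & molB$atoms$in_ring[p$b])
  atom_mapping(p[keep, , drop = FALSE], mapping$source)
}

#' Apply all three mapping sanity filters
#'
#' Convenience wrapper: ring-break, ring-size, then whole-rings-only.
#' @inheritParams filter_ringbreak
#' @return filtered [atom_mapping()].
#' @export
filter_mapping <- function(mapping, molA, molB) {
  mapping <- filter_ringbreak(mapping, molA, molB)
  mapping <- filter_ringsize(mapping, molA, molB)
  filter_whole_rings_only(mapping, molA, molB)
}

#' Same-net-charge transformation gate
#'
#' Alchemical transformations are restricted to ligand pairs with equal net
#' formal charge; changing the net charge inside a finite droplet would
#' change the long-range electrostatics between end states.
#'
#' @param molA,molB [molecule()] records.
#' @return `TRUE` iff net formal charges match.
#' @export
validate_same_charge <- function(molA, molB) {
  net_formal_charge(molA) == net_formal_charge(molB)
}

# ---------------------------------------------------------------------------
# Mapping TSV interchange (0-based indices)
# ---------------------------------------------------------------------------

#' Write a mapping as a two-column 0-based TSV
#' @param mapping an [atom_mapping()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", mapping$source), con)
  writeLines("indexA\tindexB", con)
  p <- mapping$pairs
  if (nrow(p)) writeLines(sprintf("%d\t%d", p$a - 1L, p$b - 1L), con)
  invisible(path)
}

#' Read a mapping TSV (0-based indices; manual mappings accepted)
#' @param path input path.
#' @return an [atom_mapping()]; source taken from the `# source:` header,
#'   defaulting to `"manual"`.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  src <- "manual"
  hdr <- grep("^# source:", lines, value = TRUE)
  if (length(hdr)) src <- trimws(sub("^# source:", "", hdr[1]))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  body <- body[!grepl("^indexA", body)]
  if (!length(body)) return(atom_mapping(NULL, src))
  f <- do.call(rbind, strsplit(body, "\t"))
  atom_mapping(data.frame(a = as.integer(f[, 1]) + 1L,
                          b = as.integer(f[, 2]) + 1L), src)
}
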