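# Independent brute-force oracles. These deliberately re-derive results by
# enumeration/closed form and never call the implementation paths they check.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# minimum total distance over all one-to-one assignments of rows to columns
# of distance matrix d, pairs over cutoff forbidden; returns the best total
# and the number of admissible pairs in the best assignment
brute_force_assignment <- function(d, cutoff) {
  nr <- nrow(d); nc <- ncol(d)
  stopifnot(nr <= 7, nc <= 7)
  best <- Inf; best_n <- 0L
  cols <- seq_len(nc)
  subsets <- utils::combn(nc, min(nr, nc), simplify = FALSE)
  for (sub in subsets) {
    for (p in perms(length(sub))) {
      sel <- d[cbind(seq_len(length(sub)), sub[p])]
      ok <- sel <= cutoff
      tot <- sum(sel[ok])
      # maximize mapped pairs first, then minimize distance (the matcher
      # admits every pair under cutoff it can)
      if (sum(ok) > best_n || (sum(ok) == best_n && tot < best)) {
        best <- tot; best_n <- sum(ok)
      }
    }
  }
  list(total = best, n = best_n)
}

# exhaustive simple-cycle minimal basis: enumerate all simple cycles by DFS,
# pick a GF(2)-independent basis in order of size; returns sorted sizes
cycle_basis_sizes <- function(mol) {
  bd <- mol$bonds
  n <- nrow(mol$atoms)
  if (!nrow(bd)) return(integer(0))
  adj <- vector("list", n)
  for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], bd$j[k])
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], bd$i[k])
  }
  cycles <- list()
  path <- integer(0)
  dfs <- function(v, start) {
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        cyc <- sort(path)
        key <- paste(cyc, collapse = ",")
        if (is.null(cycles[[key]])) cycles[[key]] <<- path
      } else if (!(w %in% path) && w > start) {
        dfs(w, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  if (!length(cycles)) return(integer(0))
  # edge incidence vectors over GF(2)
  ekey <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  vec <- function(cyc) {
    e <- paste(pmin(cyc, c(cyc[-1], cyc[1])), pmax(cyc, c(cyc[-1], cyc[1])))
    as.integer(ekey %in% e)
  }
  ord <- order(vapply(cycles, length, integer(1)))
  cycles <- cycles[ord]
  rank_target <- nrow(bd) - n + n_components_oracle(adj)
  basis <- matrix(integer(0), nrow = length(ekey))
  sizes <- integer(0)
  for (cyc in cycles) {
    if (length(sizes) >= rank_target) break
    v <- vec(cyc)
    if (gf2_independent(basis, v)) {
      basis <- cbind(basis, v)
      sizes <- c(sizes, length(cyc))
    }
  }
  sort(sizes)
}

n_components_oracle <- function(adj) {
  n <- length(adj); seen <- rep(FALSE, n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    q <- s; seen[s] <- TRUE
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      for (x in adj[[cur]]) if (!seen[x]) { seen[x] <- TRUE; q <- c(q, x) }
    }
  }
  comp
}

gf2_independent <- function(basis, v) {
  if (!ncol(basis)) return(any(v == 1L))
  gf2_rank(cbind(basis, v)) > gf2_rank(basis)
}

gf2_rank <- function(m) {
  m <- m %% 2L
  rank <- 0L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[, col] == 1L & seq_len(nrow(m)) > rank)
    if (!length(piv)) next
    rank <- rank + 1L
    if (piv[1] != rank) m[c(rank, piv[1]), ] <- m[c(piv[1], rank), ]
    for (r in seq_len(nrow(m))) {
      if (r != rank && m[r, col] == 1L) m[r, ] <- (m[r, ] + m[rank, ]) %% 2L
    }
  }
  rank
}

# Kendall tau-b by explicit pair enumeration with tie correction
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# dense normal-equations SFC oracle: minimize ||A g - d||^2 with the
# reference column pinned to zero, solved by explicit solve(t(A) %*% A)
sfc_oracle <- function(net, reference) {
  nodes <- net$nodes
  e <- nrow(net$edges)
  A <- matrix(0, e, length(nodes))
  A[cbind(seq_len(e), match(net$edges$from, nodes))] <- -1
  A[cbind(seq_len(e), match(net$edges$to, nodes))] <- 1
  keep <- nodes != reference
  Ar <- A[, keep, drop = FALSE]
  g <- numeric(length(nodes))
  g[keep] <- solve(t(Ar) %*% Ar, t(Ar) %*% net$edges$ddG)
  names(g) <- nodes
  g
}

# one-sided exponential-averaging estimates (kcal/mol) for bracketing checks
exp_estimates <- function(ws) {
  kT <- 0.0019872041 * ws$temperature
  lme <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  c(forward = -kT * lme(-ws$forward / kT),
    reverse = kT * lme(-ws$reverse / kT))
}

# tiny fixed-column PDB written by hand (3 protein residues + one water),
# optionally without the element column
write_toy_pdb <- function(path, with_element = TRUE) {
  fmt <- function(serial, name, resid, chain, resno, x, y, z, el, rec = "ATOM") {
    sprintf("%-6s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, resid, chain, resno, x, y, z,
            if (with_element) el else "")
  }
  lines <- c(
    fmt(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, " N"),
    fmt(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, " C"),
    fmt(3, "C",  "ALA", "A", 1, 2.2, 1.3, 0.0, " C"),
    fmt(4, "O",  "ALA", "A", 1, 3.4, 1.3, 0.0, " O"),
    fmt(5, "N",  "GLY", "A", 2, 1.6, 2.4, 0.0, " N"),
    fmt(6, "CA", "GLY", "A", 2, 2.2, 3.7, 0.0, " C"),
    fmt(7, "C",  "GLY", "A", 2, 1.2, 4.8, 0.0, " C"),
    fmt(8, "N",  "SER", "A", 3, 1.7, 6.0, 0.0, " N"),
    fmt(9, "CA", "SER", "A", 3, 0.9, 7.2, 0.0, " C"),
    fmt(10, "OG", "SER", "A", 3, 1.7, 8.4, 0.0, " O"),
    fmt(11, "O",  "HOH", "W", 101, 8.0, 8.0, 8.0, " O", "HETATM"),
    "TER", "END")
  writeLines(lines, path)
  path
}
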