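# ---------------------------------------------------------------------------
# Deterministic synthetic fixtures: toy ligand pairs with hand-derived
# expected mapping/restraint truths, Gaussian-Crooks work samples with
# known dG, networks with known node values, and toy sphere systems.
# All generators are pure functions of their arguments (and seed).
# ---------------------------------------------------------------------------

# regular n-gon in the xy plane with the given bond length, atom 1 at
# angle 0, counter-clockwise
ring_xy <- function(n, bond = 1.397) {
  r <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = r * cos(ang), y = r * sin(ang), z = 0)
}

ring_bonds <- function(n, order = 4L) {
  data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1L), order = order)
}

mk_atoms <- function(element, xyz, charge = 0L) {
  data.frame(element = element, charge = charge,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Build a named toy molecule
#'
#' Idealized heavy-atom geometries (flat rings, standard bond lengths)
#' sufficient for distance-based mapping at the default 0.95 A cutoff.
#' Available: `benzene`, `pyridine` (Kekule bond orders), `toluene`,
#' `aniline_like` (ring + N substituent), `cyclopentane`, `indole`,
#' `butane`, `carboxylate` (acetate-like, net -1), `zwitterion` (glycine-
#' like, +1/-1, net 0).
#'
#' @param name fixture name.
#' @return a [molecule()].
#' @export
fixture_molecule <- function(name) {
  hx <- ring_xy(6)
  switch(name,
    benzene = molecule("benzene", mk_atoms(rep("C", 6), hx), ring_bonds(6)),
    pyridine = {
      bd <- ring_bonds(6, order = c(2L, 1L, 2L, 1L, 2L, 1L))
      molecule("pyridine", mk_atoms(c("N", rep("C", 5)), hx), bd)
    },
    toluene = {
      xyz <- rbind(hx, c(hx[1, 1] + 1.50, 0, 0))
      bd <- rbind(ring_bonds(6), data.frame(i = 1L, j = 7L, order = 1L))
      molecule("toluene", mk_atoms(rep("C", 7), xyz), bd)
    },
    aniline_like = {
      xyz <- rbind(hx, c(hx[1, 1] + 1.40, 0, 0))
      bd <- rbind(ring_bonds(6), data.frame(i = 1L, j = 7L, order = 1L))
      molecule("aniline_like", mk_atoms(c(rep("C", 6), "N"), xyz), bd)
    },
    cyclopentane = molecule("cyclopentane",
                            mk_atoms(rep("C", 5), ring_xy(5, 1.54)),
                            ring_bonds(5, 1L)),
    indole = {
      # fused 6 + 5: hexagon atoms 1-6; five-ring shares bond 1-6 and adds
      # C7, C8, N9 on the far side
      p <- rbind(hx,
                 c(2.15, -1.70, 0),   # C7
                 c(3.35, -0.90, 0),   # C8
                 c(3.05,  0.45, 0))   # N9
      bd <- rbind(ring_bonds(6),
                  data.frame(i = c(6L, 7L, 8L, 9L), j = c(7L, 8L, 9L, 1L),
                             order = c(1L, 2L, 1L, 1L)))
      molecule("indole", mk_atoms(c(rep("C", 8), "N"), p), bd)
    },
    butane = {
      xyz <- cbind(x = c(0, 1.54, 2.3, 3.84), y = c(0, 0, 1.3, 1.3), z = 0)
      molecule("butane", mk_atoms(rep("C", 4), xyz),
               data.frame(i = 1:3, j = 2:4, order = 1L))
    },
    carboxylate = {
      # acetate-like: C-C(=O)O(-)
      xyz <- cbind(x = c(0, 1.52, 2.15, 2.15), y = c(0, 0, 1.05, -1.05), z = 0)
      molecule("carboxylate",
               mk_atoms(c("C", "C", "O", "O"), xyz,
                        charge = c(0L, 0L, 0L, -1L)),
               data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                          order = c(1L, 2L, 1L)))
    },
    zwitterion = {
      # glycine-like: N(+)-C-C(=O)O(-)
      xyz <- cbind(x = c(-1.47, 0, 1.52, 2.15, 2.15),
                   y = c(0, 0, 0, 1.05, -1.05), z = 0)
      molecule("zwitterion",
               mk_atoms(c("N", "C", "C", "O", "O"), xyz,
                        charge = c(1L, 0L, 0L, 0L, -1L)),
               data.frame(i = c(1L, 2L, 3L, 3L), j = c(2L, 3L, 4L, 5L),
                          order = c(1L, 1L, 2L, 1L)))
    },
    stop("unknown fixture molecule: ", name))
}

all_configs <- function() {
  methods <- c("element", "hybridization", "aromaticity", "heavyatom")
  strict <- c("p", "ls", "s")
  as.vector(outer(methods, strict, paste, sep = "_"))
}

pairs_df <- function(a, b) data.frame(a = as.integer(a), b = as.integer(b))

#' Toy ligand pairs with known-correct mapping and restraint answers
#'
#' Six hand-built 3D pairs covering the mapping/restraint decision space:
#' `identity` (benzene/benzene), `heteroswap` (benzene/pyridine),
#' `ringsize` (cyclopentane/benzene: filtered to nothing), `rgrowth`
#' (benzene/toluene), `syk_mimic` (shared core, distant dissimilar
#' R-groups: no restraints ever touch the R-group atoms),
#' `partial_ring` (one ring atom displaced out of mapping range, so the
#' whole-rings filter empties the ring), plus `substituent_swap`
#' (toluene vs. amino analogue separating less-strict from strict).
#'
#' Every `expected_restraints` entry was derived by hand-applying the
#' equivalence rules to the fixture geometry (enumeration over the mapped
#' pairs), independently of [set_restraints()].
#'
#' @return named list; each element has `molA`, `molB`,
#'   `expected_mapping` (pairs after the three sanity filters) and
#'   `expected_restraints`: a list keyed by config string
#'   (e.g. `"element_p"`) of expected restrained pair data.frames.
#' @export
toy_ligand_pairs <- function() {
  out <- list()
  ident6 <- pairs_df(1:6, 1:6)
  cfg <- all_configs()
  const_truth <- function(p) {
    t <- rep(list(p), length(cfg)); names(t) <- cfg; t
  }

  # 1. identity: every config keeps all six ring pairs
  out$identity <- list(
    molA = fixture_molecule("benzene"), molB = fixture_molecule("benzene"),
    expected_mapping = ident6,
    expected_restraints = const_truth(ident6))

  # 2. heteroswap: element excludes the N<->C pair (position 1); other
  # methods keep all six; strictness moot (no substituents either side)
  th <- const_truth(ident6)
  for (s in c("p", "ls", "s"))
    th[[paste0("element_", s)]] <- pairs_df(2:6, 2:6)
  out$heteroswap <- list(
    molA = fixture_molecule("benzene"), molB = fixture_molecule("pyridine"),
    expected_mapping = ident6,
    expected_restraints = th)

  # 3. ringsize: 5- vs 6-ring; the ring-size filter empties the mapping
  out$ringsize <- list(
    molA = fixture_molecule("cyclopentane"), molB = fixture_molecule("benzene"),
    expected_mapping = pairs_df(integer(), integer()),
    expected_restraints = const_truth(pairs_df(integer(), integer())))

  # 4. rgrowth: toluene's methyl is unmapped; less_strict/strict drop the
  # substituted ring position (bare vs methyl)
  tr <- const_truth(ident6)
  for (m in c("element", "hybridization", "aromaticity", "heavyatom"))
    for (s in c("ls", "s"))
      tr[[paste0(m, "_", s)]] <- pairs_df(2:6, 2:6)
  out$rgrowth <- list(
    molA = fixture_molecule("benzene"), molB = fixture_molecule("toluene"),
    expected_mapping = ident6,
    expected_restraints = tr)

  # 5. syk_mimic: shared core, far-apart dissimilar R-groups; R-group atoms
  # (7, 8 on both sides) never mapped hence never restrained; ls/s drop the
  # two substituted positions (1 on A, 4 on B)
  mkA <- {
    hx <- ring_xy(6)
    xyz <- rbind(hx, c(hx[1, 1] + 1.50, 0, 0), c(hx[1, 1] + 3.00, 0, 0))
    bd <- rbind(ring_bonds(6),
                data.frame(i = c(1L, 7L), j = c(7L, 8L), order = 1L))
    molecule("syk_mimic_A", mk_atoms(rep("C", 8), xyz), bd)
  }
  mkB <- {
    hx <- ring_xy(6)
    xyz <- rbind(hx, c(hx[4, 1] - 1.50, 0, 0), c(hx[4, 1] - 3.00, 0, 0))
    bd <- rbind(ring_bonds(6),
                data.frame(i = c(4L, 7L), j = c(7L, 8L), order = 1L))
    molecule("syk_mimic_B", mk_atoms(c(rep("C", 6), "N", "C"), xyz), bd)
  }
  ts <- const_truth(ident6)
  for (m in c("element", "hybridization", "aromaticity", "heavyatom"))
    for (s in c("ls", "s"))
      ts[[paste0(m, "_", s)]] <- pairs_df(c(2, 3, 5, 6), c(2, 3, 5, 6))
  out$syk_mimic <- list(
    molA = mkA, molB = mkB,
    expected_mapping = ident6,
    expected_restraints = ts,
    rgroup_atoms_A = 7:8, rgroup_atoms_B = 7:8)

  # 6. partial_ring: atom 6 of B displaced 2 A out of plane; only 5 of 6
  # ring atoms map, so the whole-rings filter removes the lot
  mpB <- fixture_molecule("benzene")
  mpB$atoms$z[6] <- 2.0
  mpB$name <- "benzene_displaced"
  out$partial_ring <- list(
    molA = fixture_molecule("benzene"), molB = mpB,
    expected_mapping = pairs_df(integer(), integer()),
    expected_restraints = const_truth(pairs_df(integer(), integer())))

  # 7. substituent_swap: methyl vs amino at position 1. Acyclic pair (7,7)
  # is kept by every method except element (C vs N); strict drops ring
  # position 1 (substituent elements differ)
  ident7 <- pairs_df(1:7, 1:7)
  tw <- const_truth(ident7)
  tw$element_p <- ident6
  tw$element_ls <- ident6
  tw$element_s <- pairs_df(2:6, 2:6)
  for (m in c("hybridization", "aromaticity", "heavyatom"))
    tw[[paste0(m, "_s")]] <- pairs_df(c(2:6, 7), c(2:6, 7))
  out$substituent_swap <- list(
    molA = fixture_molecule("toluene"), molB = fixture_molecule("aniline_like"),
    expected_mapping = ident7,
    expected_restraints = tw)

  out
}

# ---------------------------------------------------------------------------
# Gaussian-Crooks work generator
# ---------------------------------------------------------------------------

#' Generate Gaussian work samples consistent with the Crooks relation
#'
#' For a window with true free energy change `dG_w` and work standard
#' deviation `sigma` (kcal/mol), Gaussian forward/reverse work
#' distributions satisfying the Crooks fluctuation theorem share sigma and
#' have means dG_w + sigma^2 / (2 kT) and -dG_w + sigma^2 / (2 kT)
#' respectively. This closed-form construction is the independent ground
#' truth for BAR recovery tests.
#'
#' @param dG_w true window free energy (kcal/mol).
#' @param sigma work standard deviation (kcal/mol).
#' @param n samples per direction.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @param n_equil length of a non-equilibrium head prepended to each
#'   series (biased by a decaying +3 sigma drift) that callers are
#'   expected to discard; 0 for none.
#' @return a [work_samples()] of length `n_equil + n` per direction.
#' @export
gen_work_samples <- function(dG_w, sigma, n, temperature = 298.15, seed = 1,
                             n_equil = 0) {
  kT <- KB_KCAL * temperature
  shift <- sigma^2 / (2 * kT)
  with_preserved_rng({
    set.seed(as.integer(seed))
    fwd <- rnorm(n, mean = dG_w + shift, sd = sigma)
    rev <- rnorm(n, mean = -dG_w + shift, sd = sigma)
    if (n_equil > 0) {
      drift <- 3 * sigma * exp(-(seq_len(n_equil) - 1) / 20)
      fwd <- c(rnorm(n_equil, dG_w + shift, sigma) + drift, fwd)
      rev <- c(rnorm(n_equil, -dG_w + shift, sigma) + drift, rev)
    }
    work_samples(fwd, rev, temperature)
  })
}

#' Write a replicate leg of Gaussian-Crooks work files
#'
#' Partitions `dG_true` equally across `n_windows` adjacent window pairs
#' and writes `pair_###.fwd` / `pair_###.rev` two-column (step, dU) files
#' into `dir`, each with an `n_equil`-sample non-equilibrium head.
#'
#' @param dir output directory (created).
#' @param dG_true total leg free energy (kcal/mol).
#' @param sigma per-window work standard deviation (kcal/mol).
#' @param n_windows number of adjacent window pairs.
#' @param n_samples production samples per direction per window.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @param n_equil discardable head length (default 100).
#' @return (invisibly) the per-window true dG vector.
#' @export
gen_bar_samples <- function(dir, dG_true, sigma, n_windows, n_samples,
                            temperature = 298.15, seed = 1, n_equil = 100) {
  stopifnot(n_windows >= 1, n_samples > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dG_w <- rep(dG_true / n_windows, n_windows)
  for (w in seq_len(n_windows)) {
    ws <- gen_work_samples(dG_w[w], sigma, n_samples, temperature,
                           seed = seed * 1000L + w, n_equil = n_equil)
    write_series <- function(x, path) {
      writeLines(c("# step dU_kcal_mol",
                   sprintf("%d %.10g", seq_along(x), x)), path)
    }
    write_series(ws$forward, file.path(dir, sprintf("pair_%03d.fwd", w)))
    write_series(ws$reverse, file.path(dir, sprintf("pair_%03d.rev", w)))
  }
  invisible(dG_w)
}

#' Write a full synthetic edge directory (both legs, all replicates)
#'
#' @param edge_dir output directory.
#' @param dG_protein,dG_water true leg free energies (kcal/mol); the true
#'   edge ddG_bind is their difference.
#' @param sigma per-window work standard deviation.
#' @param n_windows window pairs per leg.
#' @param n_samples production samples per direction per window.
#' @param replicates replicates per leg.
#' @param temperature Kelvin.
#' @param seed integer master seed.
#' @param n_equil discardable head length.
#' @return `edge_dir`, invisibly.
#' @export
gen_edge_data <- function(edge_dir, dG_protein, dG_water, sigma = 1,
                          n_windows = 5, n_samples = 500, replicates = 3,
                          temperature = 298.15, seed = 1, n_equil = 100) {
  legs <- c(protein = dG_protein, water = dG_water)
  k <- 0L
  for (leg in names(legs)) {
    for (rep in seq_len(replicates)) {
      k <- k + 1L
      gen_bar_samples(file.path(edge_dir, leg, sprintf("replicate_%02d", rep)),
                      legs[[leg]], sigma, n_windows, n_samples, temperature,
                      seed = seed + 7919L * k, n_equil = n_equil)
    }
  }
  invisible(edge_dir)
}

# ---------------------------------------------------------------------------
# Network generator
# ---------------------------------------------------------------------------

#' Generate a perturbation network with known node free energies
#'
#' Draws true node values uniformly on `dg_range`, builds the requested
#' topology, and sets each edge to the true difference plus N(0, sigma^2)
#' noise.
#'
#' @param n_nodes number of ligands (>= 2).
#' @param topology `"star"` (node 1 hub), `"cycle"`, or `"dense"`
#'   (complete graph).
#' @param dg_range range of true node dG values (kcal/mol).
#' @param sigma edge noise standard deviation (kcal/mol).
#' @param seed integer seed.
#' @param extra_chords for `"cycle"`: number of additional random chords.
#' @return list `net` (a [perturbation_network()]), `truth` (named numeric
#'   of true node dG), `noise` (per-edge noise draws).
#' @export
gen_network <- function(n_nodes, topology = c("star", "cycle", "dense"),
                        dg_range = c(-12, -6), sigma = 0, seed = 1,
                        extra_chords = 0) {
  stopifnot(n_nodes >= 2)
  topology <- match.arg(topology)
  ids <- sprintf("lig%02d", seq_len(n_nodes))
  with_preserved_rng({
    set.seed(as.integer(seed))
    truth <- structure(runif(n_nodes, dg_range[1], dg_range[2]), names = ids)
    ep <- switch(topology,
      star = cbind(1L, seq_len(n_nodes)[-1]),
      cycle = cbind(seq_len(n_nodes), c(seq_len(n_nodes)[-1], 1L)),
      dense = t(utils::combn(n_nodes, 2)))
    if (topology == "cycle" && extra_chords > 0) {
      avail <- t(utils::combn(n_nodes, 2))
      key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      avail <- avail[!(key(avail) %in% key(ep)), , drop = FALSE]
      take <- sample(nrow(avail), min(extra_chords, nrow(avail)))
      ep <- rbind(ep, avail[take, , drop = FALSE])
    }
    noise <- rnorm(nrow(ep), 0, sigma)
    edges <- data.frame(from = ids[ep[, 1]], to = ids[ep[, 2]],
                        ddG = truth[ep[, 2]] - truth[ep[, 1]] + noise,
                        sem = rep(max(sigma, 1e-3), nrow(ep)))
    list(net = perturbation_network(edges), truth = truth, noise = noise)
  })
}

# ---------------------------------------------------------------------------
# Toy sphere system
# ---------------------------------------------------------------------------

#' Random atoms at controlled radii with known inside/outside truth
#'
#' Places `n_atoms` points uniformly on random directions, a controlled
#' fraction at radii beyond `radius` (1.05-1.6 r) and the rest inside
#' (0-0.95 r), and records the ground-truth classification.
#'
#' @param n_atoms number of atoms.
#' @param fraction_outside fraction placed beyond the sphere radius.
#' @param radius sphere radius (Angstrom, default 25).
#' @param center sphere center.
#' @param seed integer seed.
#' @return list `xyz`, `outside` (logical truth), `center`, `radius`.
#' @export
toy_sphere_system <- function(n_atoms, fraction_outside = 0.35, radius = 25,
                              center = c(0, 0, 0), seed = 1) {
  n_out <- round(n_atoms * fraction_outside)
  with_preserved_rng({
    set.seed(as.integer(seed))
    u <- matrix(rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- c(runif(n_atoms - n_out, 0, 0.95 * radius),
           runif(n_out, 1.05 * radius, 1.6 * radius))
    xyz <- sweep(u * r, 2, center, "+")
    list(xyz = xyz, outside = c(rep(FALSE, n_atoms - n_out), rep(TRUE, n_out)),
         center = center, radius = radius)
  })
}
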