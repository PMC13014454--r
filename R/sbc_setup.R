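# ---------------------------------------------------------------------------
# Spherical-boundary system construction: sphere placement, boundary
# classification, lattice solvation with clearance, ligand-clash water
# removal, dual-topology merge.
# ---------------------------------------------------------------------------

#' Geometric center for sphere placement
#'
#' Unweighted centroid of all heavy atoms across the given ligand(s); with
#' two end-state ligands the union centroid is used so the droplet covers
#' both topologies.
#'
#' @param ... one or two [molecule()] records.
#' @return numeric length-3 vector (Angstrom).
#' @export
sphere_center <- function(...) {
  mols <- list(...)
  if (length(mols) == 1L && is.list(mols[[1]]) && !inherits(mols[[1]], "molecule"))
    mols <- mols[[1]]
  xyz <- do.call(rbind, lapply(mols, coords, heavy_only = TRUE))
  if (is.null(xyz) || nrow(xyz) == 0L) stop("no heavy atoms to center on")
  colMeans(xyz)
}

#' Classify atoms against the simulation sphere
#'
#' Atoms farther than `radius` from the sphere center are boundary-
#' constrained with a harmonic force constant (default 200 kcal/mol/A^2);
#' atoms inside move freely. Classification is per atom, never per residue.
#'
#' @param xyz numeric matrix of atom positions (rows, x/y/z in Angstrom).
#' @param center sphere center, length-3.
#' @param radius sphere radius in Angstrom (default 25).
#' @param k_boundary harmonic constant for constrained atoms, kcal/mol/A^2.
#' @return data.frame with `distance`, `class` ("free" or "boundary"), `k`
#'   (0 for free atoms).
#' @export
classify_sphere_atoms <- function(xyz, center, radius = 25, k_boundary = 200) {
  stopifnot(radius > 0)
  xyz <- as.matrix(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, center)^2))
  outside <- d > radius
  data.frame(distance = d,
             class = ifelse(outside, "boundary", "free"),
             k = ifelse(outside, k_boundary, 0))
}

#' Build an (unsolvated) sphere system
#'
#' @param center sphere center (Angstrom).
#' @param radius sphere radius, Angstrom (default 25).
#' @param solute_xyz matrix of solute atom positions (protein + ligand);
#'   may have zero rows for an empty droplet.
#' @param solute_heavy logical per solute atom; defaults to all TRUE.
#' @param k_boundary boundary harmonic constant, kcal/mol/A^2 (default 200).
#' @return object of class `sphere_system` (no waters yet; see
#'   [solvate_sphere()]).
#' @export
sphere_system <- function(center, radius = 25, solute_xyz = NULL,
                          solute_heavy = NULL, k_boundary = 200) {
  stopifnot(length(center) == 3L, radius > 0)
  if (is.null(solute_xyz)) solute_xyz <- matrix(numeric(), ncol = 3)
  solute_xyz <- as.matrix(solute_xyz)
  if (is.null(solute_heavy)) solute_heavy <- rep(TRUE, nrow(solute_xyz))
  cls <- if (nrow(solute_xyz))
    classify_sphere_atoms(solute_xyz, center, radius, k_boundary)
  else data.frame(distance = numeric(), class = character(), k = numeric())
  structure(list(center = as.numeric(center), radius = radius,
                 solute_xyz = solute_xyz, solute_heavy = solute_heavy,
                 solute_class = cls, k_boundary = k_boundary,
                 waters = matrix(numeric(), ncol = 3), dual = NULL,
                 removed_waters = 0L),
            class = "sphere_system")
}

#' @export
print.sphere_system <- function(x, ...) {
  cat(sprintf("<sphere_system> r = %g A at (%.2f, %.2f, %.2f); %d solute atom(s) (%d boundary-constrained), %d water(s)\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              nrow(x$solute_xyz), sum(x$solute_class$class == "boundary"),
              nrow(x$waters)))
  invisible(x)
}

#' Solvate a sphere with lattice water
#'
#' Water oxygens are placed on a regular cubic lattice (default spacing
#' 3.107 A, bulk TIP3P density) anchored at the sphere center, clipped to
#' the sphere, then any water closer than `clearance` to a solute heavy
#' atom is dropped. Deterministic for fixed spacing and origin.
#'
#' @param system a [sphere_system()].
#' @param clearance minimum water-oxygen to solute-heavy-atom distance,
#'   Angstrom (default 3.0).
#' @param spacing lattice constant, Angstrom.
#' @return the system with `waters` filled (oxygen positions; hydrogens are
#'   generated at write-out with a fixed geometry).
#' @export
solvate_sphere <- function(system, clearance = 3.0, spacing = 3.107) {
  stopifnot(inherits(system, "sphere_system"))
  if (clearance >= system$radius)
    stop("clearance must be smaller than the sphere radius")
  w <- water_lattice(system$center, system$radius, spacing)
  if (nrow(w) && nrow(system$solute_xyz)) {
    heavy <- system$solute_xyz[system$solute_heavy, , drop = FALSE]
    if (nrow(heavy)) {
      dmin <- min_dist_to_set(w, heavy)
      w <- w[dmin >= clearance, , drop = FALSE]
    }
  }
  system$waters <- w
  system$clearance <- clearance
  system$spacing <- spacing
  system
}

# cubic lattice points within radius of center (center is a lattice point)
water_lattice <- function(center, radius, spacing) {
  kmax <- floor(radius / spacing)
  g <- seq(-kmax, kmax) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[sqrt(rowSums(pts^2)) <= radius, , drop = FALSE]
  pts <- sweep(pts, 2, center, "+")
  pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
}

# for each row of a, min distance to any row of b
min_dist_to_set <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Remove waters clashing with either end-state ligand
#'
#' During edge creation both dual-topology ligands occupy the site; any
#' water within `cutoff` of *any* atom of either ligand is removed (the
#' removal count is recorded on the system).
#'
#' @param system a solvated [sphere_system()].
#' @param dual a [dual_topology()].
#' @param cutoff clash distance in Angstrom (default 3.0, the solvation
#'   clearance).
#' @return the system with clashing waters removed.
#' @export
remove_clashing_waters <- function(system, dual, cutoff = 3.0) {
  stopifnot(inherits(system, "sphere_system"), inherits(dual, "dual_topology"))
  if (!nrow(system$waters)) return(system)
  lig <- dual$xyz
  dmin <- min_dist_to_set(system$waters, lig)
  clash <- dmin < cutoff
  system$removed_waters <- system$removed_waters + sum(clash)
  system$waters <- system$waters[!clash, , drop = FALSE]
  system
}

# ---------------------------------------------------------------------------
# Dual topology
# ---------------------------------------------------------------------------

#' Merge two ligands into a dual topology
#'
#' Both end-state ligands coexist: the merged atom list is all atoms of A
#' followed by all atoms of B (A indices unchanged, B offset by |A|), with
#' complementary per-state presence masks (state 0: A on / B off; state 1:
#' A off / B on). No bonds connect the two blocks; cross-topology restraint
#' indices are re-expressed in merged numbering.
#'
#' @param molA,molB [molecule()] records with coordinates.
#' @param restraints a [restraint_set()] on (A, B) indices.
#' @return object of class `dual_topology` with `xyz`, `element`, `n_A`,
#'   `n_B`, `mask_state0`, `mask_state1`, and `restraints_merged`
#'   (data.frame `i`, `j`, `k`, `activation` in merged indices).
#' @export
build_dual_topology <- function(molA, molB, restraints = restraint_set(NULL)) {
  nA <- nrow(molA$atoms); nB <- nrow(molB$atoms)
  p <- restraints$pairs
  if (nrow(p) && (any(p$a < 1L | p$a > nA) || any(p$b < 1L | p$b > nB)))
    stop("restraint references an atom outside the ligands")
  xyz <- rbind(coords(molA), coords(molB))
  structure(list(
    xyz = xyz,
    element = c(molA$atoms$element, molB$atoms$element),
    n_A = nA, n_B = nB,
    mask_state0 = c(rep(TRUE, nA), rep(FALSE, nB)),
    mask_state1 = c(rep(FALSE, nA), rep(TRUE, nB)),
    restraints_merged = data.frame(i = p$a, j = p$b + nA,
                                   k = p$k, activation = p$activation),
    restraints = restraints),
    class = "dual_topology")
}

#' @export
print.dual_topology <- function(x, ...) {
  cat(sprintf("<dual_topology> %d + %d atoms, %d cross-topology restraint(s)\n",
              x$n_A, x$n_B, nrow(x$restraints_merged)))
  invisible(x)
}

#' Attach a dual-topology ligand payload to a sphere system
#' @param system a [sphere_system()].
#' @param dual a [dual_topology()].
#' @return the system with the dual payload attached.
#' @export
attach_dual_topology <- function(system, dual) {
  stopifnot(inherits(dual, "dual_topology"))
  system$dual <- dual
  system
}

#' Write a sphere system to disk
#'
#' Emits the droplet PDB (solute placeholder residues + SPC-geometry
#' waters), a TSV of boundary-constrained solute atom indices with the
#' harmonic constant, a removed-water log, and a JSON-like run manifest
#' (center, radius, clearance, counts).
#'
#' @param system a solvated [sphere_system()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sphere_system <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ns <- nrow(system$solute_xyz)
  sol <- if (ns) data.frame(
    element = rep("C", ns), name = "X", resid = "SOL", resno = seq_len(ns),
    chain = "A",
    x = system$solute_xyz[, 1], y = system$solute_xyz[, 2],
    z = system$solute_xyz[, 3]) else NULL
  wat <- water_geometry(system$waters)
  atoms <- rbind(sol, wat)
  write_pdb(atoms, file.path(dir, "droplet.pdb"))
  bc <- which(system$solute_class$class == "boundary")
  writeLines(c("index\tk",
               sprintf("%d\t%g", bc - 1L, system$k_boundary)),
             file.path(dir, "boundary.tsv"))
  writeLines(c("removed_waters", as.character(system$removed_waters)),
             file.path(dir, "removed_waters.tsv"))
  manifest <- sprintf(
    '{"center": [%.4f, %.4f, %.4f], "radius": %g, "clearance": %g, "n_solute": %d, "n_boundary": %d, "n_waters": %d, "removed_waters": %d}',
    system$center[1], system$center[2], system$center[3], system$radius,
    system$clearance %||% NA_real_, ns, length(bc), nrow(system$waters),
    system$removed_waters)
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

# expand oxygen lattice to 3-site waters with fixed orientation
# (OH 0.9572 A, HOH 104.52 deg)
water_geometry <- function(o_xyz) {
  n <- nrow(o_xyz)
  if (!n) return(NULL)
  r <- 0.9572
  half <- 104.52 / 2 * pi / 180
  h1 <- c(r * sin(half),  r * cos(half), 0)
  h2 <- c(-r * sin(half), r * cos(half), 0)
  res <- do.call(rbind, lapply(seq_len(n), function(i) {
    o <- o_xyz[i, ]
    data.frame(element = c("O", "H", "H"),
               name = c("OW", "HW1", "HW2"),
               resid = "HOH", resno = i, chain = "W",
               x = c(o[1], o[1] + h1[1], o[1] + h2[1]),
               y = c(o[2], o[2] + h1[2], o[2] + h2[2]),
               z = c(o[3], o[3] + h1[3], o[3] + h2[3]))
  }))
  rownames(res) <- NULL
  res
}
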