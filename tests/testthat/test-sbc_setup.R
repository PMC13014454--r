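test_that("sphere center is the heavy-atom centroid", {
  one <- molecule("pt", data.frame(element = "C", charge = 0L,
                                   x = 1, y = 2, z = 3),
                  data.frame(i = integer(), j = integer(), order = integer()))
  expect_equal(sphere_center(one), c(x = 1, y = 2, z = 3), ignore_attr = TRUE)
  two <- molecule("pts", data.frame(element = c("C", "C"), charge = 0L,
                                    x = c(0, 2), y = 0, z = 0),
                  data.frame(i = 1L, j = 2L, order = 1L))
  expect_equal(unname(sphere_center(two)), c(1, 0, 0))
  benz <- fixture_molecule("benzene")
  expect_equal(unname(sphere_center(benz)),
               unname(colMeans(coords(benz))), tolerance = 1e-6)
  # union centroid over two ligands
  expect_equal(unname(sphere_center(two, two)), c(1, 0, 0))
  # hydrogens are ignored
  h_only <- molecule("h", data.frame(element = "H", charge = 0L,
                                     x = 0, y = 0, z = 0),
                     data.frame(i = integer(), j = integer(), order = integer()))
  expect_error(sphere_center(h_only), "heavy")
})

test_that("boundary classification agrees with an independent distance oracle", {
  toy <- toy_sphere_system(1000, fraction_outside = 0.4, radius = 25,
                           center = c(3, -2, 7), seed = 11)
  cls <- classify_sphere_atoms(toy$xyz, toy$center, toy$radius)
  oracle <- sqrt((toy$xyz[, 1] - 3)^2 + (toy$xyz[, 2] + 2)^2 +
                 (toy$xyz[, 3] - 7)^2) > 25
  expect_equal(cls$class == "boundary", oracle)
  expect_equal(cls$class == "boundary", toy$outside)
  expect_true(all(cls$k[cls$class == "boundary"] == 200))
  expect_true(all(cls$k[cls$class == "free"] == 0))
})

test_that("boundary cases classify per atom at the radius", {
  cls <- classify_sphere_atoms(rbind(c(24.9, 0, 0), c(25.1, 0, 0)),
                               c(0, 0, 0), 25)
  expect_equal(cls$class, c("free", "boundary"))
})

test_that("empty-sphere water count equals the lattice enumeration oracle", {
  ss <- solvate_sphere(sphere_system(c(0, 0, 0), radius = 6), clearance = 3,
                       spacing = 3.1)
  # independent enumeration: integer triples with spacing-scaled norm <= r
  kmax <- floor(6 / 3.1)
  cnt <- 0L
  for (i in -kmax:kmax) for (j in -kmax:kmax) for (k in -kmax:kmax)
    if ((i^2 + j^2 + k^2) * 3.1^2 <= 36) cnt <- cnt + 1L
  expect_equal(nrow(ss$waters), cnt)
  expect_true(all(sqrt(rowSums(ss$waters^2)) <= 6))
})

test_that("solvation honours the clearance and is monotone in it", {
  solute <- rbind(c(0, 0, 0))
  base <- sphere_system(c(0, 0, 0), radius = 10, solute_xyz = solute)
  s3 <- solvate_sphere(base, clearance = 3.0)
  expect_true(all(min_dist <- sqrt(rowSums(s3$waters^2)) >= 3.0))
  s6 <- solvate_sphere(base, clearance = 6.0)
  expect_lte(nrow(s6$waters), nrow(s3$waters))
  expect_error(solvate_sphere(base, clearance = 11), "radius")
})

test_that("water count scales roughly with sphere volume", {
  n5 <- nrow(solvate_sphere(sphere_system(c(0, 0, 0), 5))$waters)
  n10 <- nrow(solvate_sphere(sphere_system(c(0, 0, 0), 10))$waters)
  expect_lt(abs(n10 / n5 - 8), 0.15 * 8)
})

test_that("clash removal considers both end-state ligands", {
  benz <- fixture_molecule("benzene")
  shifted <- benz
  shifted$atoms$x <- shifted$atoms$x + 6   # B occupies new space
  dual <- build_dual_topology(benz, shifted)
  ss <- solvate_sphere(sphere_system(c(3, 0, 0), radius = 12,
                                     solute_xyz = matrix(c(50, 50, 50), 1)),
                       clearance = 3)
  onlyA <- build_dual_topology(benz, benz)
  afterA <- remove_clashing_waters(ss, onlyA, cutoff = 2.5)
  afterAB <- remove_clashing_waters(ss, dual, cutoff = 2.5)
  expect_lte(nrow(afterAB$waters), nrow(afterA$waters))
  # no water within the cutoff of any atom of either ligand
  d <- as.matrix(dist(rbind(afterAB$waters, dual$xyz)))
  nw <- nrow(afterAB$waters)
  expect_true(all(d[seq_len(nw), nw + seq_len(nrow(dual$xyz))] >= 2.5))
  expect_equal(afterAB$removed_waters,
               nrow(ss$waters) - nrow(afterAB$waters))
  # a water 1.5 A from a B-only atom must go at cutoff 2.0
  wtest <- ss
  wtest$waters <- rbind(c(6 + 1.397 + 1.5, 0, 0))
  out <- remove_clashing_waters(wtest, dual, cutoff = 2.0)
  expect_equal(nrow(out$waters), 0L)
})

test_that("dual topology concatenates blocks with complementary masks", {
  fx <- toy_ligand_pairs()$rgrowth    # |A| = 6, |B| = 7
  m <- filter_mapping(map_by_distance(fx$molA, fx$molB), fx$molA, fx$molB)
  rs <- set_restraints(fx$molA, fx$molB, m)
  dual <- build_dual_topology(fx$molA, fx$molB, rs)
  expect_equal(nrow(dual$xyz), 13L)
  expect_equal(sum(dual$mask_state0), 6L)
  expect_equal(sum(dual$mask_state1), 7L)
  expect_true(all(xor(dual$mask_state0, dual$mask_state1)))
  # restraint indices offset by |A| on the B side
  expect_equal(dual$restraints_merged$j, rs$pairs$b + 6L)
  expect_equal(dual$restraints_merged$i, rs$pairs$a)
  # both ligands keep their input coordinates
  expect_equal(dual$xyz[1:6, ], coords(fx$molA))
  expect_equal(dual$xyz[7:13, ], coords(fx$molB))
  # restraint referencing a missing atom errors
  bad <- restraint_set(data.frame(a = 99L, b = 1L, k = 0.5, activation = 0.1,
                                  provenance = "ring match"))
  expect_error(build_dual_topology(fx$molA, fx$molB, bad), "outside")
})

test_that("system invariants hold after solvate + clash removal", {
  benz <- fixture_molecule("benzene")
  tol <- fixture_molecule("toluene")
  dual <- build_dual_topology(benz, tol)
  prot <- toy_sphere_system(40, 0.3, radius = 12, seed = 4)
  sys <- sphere_system(c(0, 0, 0), radius = 12, solute_xyz = prot$xyz)
  sys <- solvate_sphere(sys, clearance = 3.0)
  sys <- remove_clashing_waters(sys, dual, cutoff = 3.0)
  # every atom outside the radius is boundary-constrained
  d <- sqrt(rowSums(sys$solute_xyz^2))
  expect_equal(sys$solute_class$class == "boundary", d > 12)
  # every water oxygen inside the radius and clear of solute heavy atoms
  expect_true(all(sqrt(rowSums(sys$waters^2)) <= 12))
  if (nrow(sys$waters)) {
    dmin <- min(as.matrix(dist(rbind(sys$waters, prot$xyz)))[
      seq_len(nrow(sys$waters)), nrow(sys$waters) + seq_len(nrow(prot$xyz))])
    expect_gte(dmin, 3.0)
  }
})

test_that("sphere system writes droplet PDB, boundary TSV and manifest", {
  dir <- withr::local_tempdir()
  prot <- toy_sphere_system(20, 0.35, radius = 10, seed = 2)
  sys <- sphere_system(c(0, 0, 0), 10, prot$xyz)
  sys <- solvate_sphere(sys, 3.0)
  write_sphere_system(sys, dir)
  expect_true(all(file.exists(file.path(dir, c("droplet.pdb", "boundary.tsv",
                                               "removed_waters.tsv",
                                               "manifest.json")))))
  bt <- read.table(file.path(dir, "boundary.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(bt), sum(prot$outside))
  expect_true(all(bt$k == 200))
  back <- read_pdb(file.path(dir, "droplet.pdb"))
  expect_equal(sum(back$atoms$is_water), 3L * nrow(sys$waters))
})
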