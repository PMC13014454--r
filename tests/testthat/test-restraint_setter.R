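test_that("atom-level equivalence follows the four criteria", {
  benz <- fixture_molecule("benzene")   # aromatic sp2 C
  pyr <- fixture_molecule("pyridine")   # atom 1 = aromatic N
  tol <- fixture_molecule("toluene")    # atom 7 = sp3 C
  # aromatic C vs aromatic N: equivalent under aromaticity, not element
  expect_true(atoms_equivalent(benz, 1, pyr, 1, "aromaticity"))
  expect_false(atoms_equivalent(benz, 1, pyr, 1, "element"))
  # sp2 C vs sp3 C: hybridization no, heavyatom yes
  expect_false(atoms_equivalent(benz, 1, tol, 7, "hybridization"))
  expect_true(atoms_equivalent(benz, 1, tol, 7, "heavyatom"))
  expect_true(atoms_equivalent(benz, 1, pyr, 1, "hybridization"))
})

test_that("hydrogen input is a contract violation", {
  h <- molecule("h2", data.frame(element = c("H", "H"), charge = 0L,
                                 x = c(0, 0.74), y = 0, z = 0),
                data.frame(i = 1L, j = 2L, order = 1L))
  benz <- fixture_molecule("benzene")
  expect_error(atoms_equivalent(h, 1, benz, 1, "heavyatom"), "heavy")
})

test_that("ring correspondences need a majority of mapped atoms", {
  benz <- fixture_molecule("benzene")
  pyr <- fixture_molecule("pyridine")
  full <- atom_mapping(data.frame(a = 1:6, b = 1:6))
  rc <- ring_correspondences(full, benz, pyr)
  expect_equal(nrow(rc), 1L)
  # exactly half (3 of 6) is not a strict majority
  half <- atom_mapping(data.frame(a = 1:3, b = 1:3), "manual")
  expect_equal(nrow(ring_correspondences(half, benz, pyr)), 0L)
  four <- atom_mapping(data.frame(a = 1:4, b = 1:4), "manual")
  expect_equal(nrow(ring_correspondences(four, benz, pyr)), 1L)
  # unmapped rings give no correspondence
  expect_equal(nrow(ring_correspondences(atom_mapping(NULL), benz, pyr)), 0L)
})

test_that("two separate mapped rings give two correspondences", {
  # indole vs indole identity: both rings correspond
  ind <- fixture_molecule("indole")
  m <- map_by_distance(ind, ind)
  rc <- ring_correspondences(m, ind, ind)
  expect_equal(nrow(rc), 2L)
  expect_equal(rc$ringA, rc$ringB)
})

test_that("substituent equivalence implements the three strictness levels", {
  tol <- fixture_molecule("toluene")       # position 1: methyl (C)
  ani <- fixture_molecule("aniline_like")  # position 1: amino (N)
  benz <- fixture_molecule("benzene")      # bare
  # methyl vs amino: less_strict passes (one heavy substituent each),
  # strict fails (C vs N)
  expect_true(substituents_equivalent(tol, 1, ani, 1, "less_strict"))
  expect_false(substituents_equivalent(tol, 1, ani, 1, "strict"))
  expect_true(substituents_equivalent(tol, 1, ani, 1, "permissive"))
  # both bare: any strictness passes
  for (s in c("permissive", "less_strict", "strict"))
    expect_true(substituents_equivalent(benz, 2, tol, 2, s))
  # methyl vs bare: less_strict fails
  expect_false(substituents_equivalent(tol, 1, benz, 1, "less_strict"))
})

test_that("emitted restraint sets equal the hand-derived fixture truths", {
  for (nm in names(toy_ligand_pairs())) {
    fx <- toy_ligand_pairs()[[nm]]
    m <- suppressWarnings(filter_mapping(map_by_distance(fx$molA, fx$molB),
                                         fx$molA, fx$molB))
    for (cfg in names(fx$expected_restraints)) {
      rs <- suppressWarnings(set_restraints(fx$molA, fx$molB, m, cfg))
      got <- rs$pairs[order(rs$pairs$a), c("a", "b")]
      rownames(got) <- NULL
      expect_equal(got, fx$expected_restraints[[cfg]],
                   label = paste(nm, cfg))
      expect_equal(unique(rs$pairs$k), if (nrow(rs$pairs)) 0.5 else numeric(0))
      expect_equal(unique(rs$pairs$activation),
                   if (nrow(rs$pairs)) 0.1 else numeric(0))
    }
  }
})

test_that("syk-mimic R-group atoms receive zero restraints under every config", {
  fx <- toy_ligand_pairs()$syk_mimic
  m <- filter_mapping(map_by_distance(fx$molA, fx$molB), fx$molA, fx$molB)
  for (cfg in names(fx$expected_restraints)) {
    rs <- set_restraints(fx$molA, fx$molB, m, cfg)
    expect_false(any(rs$pairs$a %in% fx$rgroup_atoms_A))
    expect_false(any(rs$pairs$b %in% fx$rgroup_atoms_B))
  }
})

test_that("strictness and method inclusions are monotone on all fixtures", {
  key <- function(rs) paste(rs$pairs$a, rs$pairs$b)
  for (fx in toy_ligand_pairs()) {
    m <- suppressWarnings(filter_mapping(map_by_distance(fx$molA, fx$molB),
                                         fx$molA, fx$molB))
    for (meth in c("element", "hybridization", "aromaticity", "heavyatom")) {
      s <- suppressWarnings(set_restraints(fx$molA, fx$molB, m,
                                           equivalence_config(meth, "strict")))
      ls <- suppressWarnings(set_restraints(fx$molA, fx$molB, m,
                                            equivalence_config(meth, "less_strict")))
      p <- suppressWarnings(set_restraints(fx$molA, fx$molB, m,
                                           equivalence_config(meth, "permissive")))
      expect_true(all(key(s) %in% key(ls)))
      expect_true(all(key(ls) %in% key(p)))
    }
    for (str in c("permissive", "less_strict", "strict")) {
      el <- suppressWarnings(set_restraints(fx$molA, fx$molB, m,
                                            equivalence_config("element", str)))
      ha <- suppressWarnings(set_restraints(fx$molA, fx$molB, m,
                                            equivalence_config("heavyatom", str)))
      expect_true(all(key(el) %in% key(ha)))
    }
  }
})

test_that("restraint output is invariant under relabeling A and B", {
  for (fx in toy_ligand_pairs()) {
    m <- suppressWarnings(filter_mapping(map_by_distance(fx$molA, fx$molB),
                                         fx$molA, fx$molB))
    m_t <- atom_mapping(data.frame(a = m$pairs$b, b = m$pairs$a), m$source)
    for (cfg in c("heavyatom_p", "element_ls", "hybridization_s")) {
      fwd <- suppressWarnings(set_restraints(fx$molA, fx$molB, m, cfg))
      rev <- suppressWarnings(set_restraints(fx$molB, fx$molA, m_t, cfg))
      expect_equal(data.frame(a = sort(fwd$pairs$a), b = fwd$pairs$b[order(fwd$pairs$a)]),
                   data.frame(a = sort(rev$pairs$b), b = rev$pairs$a[order(rev$pairs$b)]),
                   label = paste(fx$molA$name, cfg))
    }
  }
})

test_that("every emitted pair is heavy, mapped, and unique", {
  for (fx in toy_ligand_pairs()) {
    m <- suppressWarnings(filter_mapping(map_by_distance(fx$molA, fx$molB),
                                         fx$molA, fx$molB))
    rs <- suppressWarnings(set_restraints(fx$molA, fx$molB, m))
    if (!nrow(rs$pairs)) next
    expect_true(all(fx$molA$atoms$heavy[rs$pairs$a]))
    expect_true(all(fx$molB$atoms$heavy[rs$pairs$b]))
    mk <- paste(m$pairs$a, m$pairs$b)
    expect_true(all(paste(rs$pairs$a, rs$pairs$b) %in% mk))
    expect_equal(anyDuplicated(rs$pairs[, c("a", "b")]), 0L)
  }
})

test_that("empty mapping yields an empty restraint set with a warning", {
  benz <- fixture_molecule("benzene")
  expect_warning(rs <- set_restraints(benz, benz, atom_mapping(NULL)), "empty")
  expect_equal(nrow(rs$pairs), 0L)
})

test_that("restraint TSV round-trips pairs, constants and config", {
  fx <- toy_ligand_pairs()$heteroswap
  m <- filter_mapping(map_by_distance(fx$molA, fx$molB), fx$molA, fx$molB)
  rs <- set_restraints(fx$molA, fx$molB, m, "element_ls")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rs, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "config: element_ls")
  expect_true(any(grepl("^# excluded: 0 0 \\(atom_compare:element\\)", lines)))
  back <- read_restraints(tf)
  expect_equal(back$pairs[, c("a", "b", "k", "activation")],
               rs$pairs[, c("a", "b", "k", "activation")])
  expect_equal(format_equivalence_config(back$config), "element_ls")
})

test_that("config strings parse and format with the suffix convention", {
  for (s in c("element_p", "hybridization_ls", "aromaticity_s", "heavyatom_p"))
    expect_equal(format_equivalence_config(parse_equivalence_config(s)), s)
  expect_error(parse_equivalence_config("carbon_p"), "unrecognised")
})
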