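tri <- function(ddG_ac) {
  perturbation_network(data.frame(from = c("a", "b", "a"),
                                  to = c("b", "c", "c"),
                                  ddG = c(1, 1, ddG_ac)))
}

test_that("most connected node wins; ties break lexicographically", {
  star <- perturbation_network(data.frame(from = "hub",
                                          to = c("x", "y", "z"),
                                          ddG = c(1, 2, 3)))
  expect_equal(most_connected_node(star), "hub")
  expect_equal(most_connected_node(tri(2)), "a")   # all degree 2 -> first
  path <- perturbation_network(data.frame(from = c("a", "b"),
                                          to = c("b", "c"), ddG = c(1, 1)))
  expect_equal(most_connected_node(path), "b")
})

test_that("consistent networks are recovered exactly", {
  nfe <- sfc_correct(tri(2), reference = "a")
  expect_equal(nfe$nodes$dG, c(0, 1, 2), tolerance = 1e-12)
  expect_equal(max(abs(nfe$residuals$residual)), 0, tolerance = 1e-12)
  two <- perturbation_network(data.frame(from = "a", to = "b", ddG = 1.7))
  expect_equal(sfc_correct(two, reference = "a")$nodes$dG, c(0, 1.7))
})

test_that("inconsistent triangle matches the dense normal-equations oracle", {
  net <- tri(2.5)
  nfe <- sfc_correct(net, reference = "a")
  oracle <- sfc_oracle(net, "a")
  expect_equal(structure(nfe$nodes$dG, names = nfe$nodes$node), oracle,
               tolerance = 1e-10)
  # least squares: perturbing the solution never lowers the residual SSQ
  ssq <- function(g) sum((g[net$edges$to] - g[net$edges$from] - net$edges$ddG)^2)
  base <- ssq(oracle)
  set.seed(5)
  for (k in 1:25) {
    pert <- oracle + c(0, rnorm(2, 0, 0.05))
    names(pert) <- names(oracle)
    expect_gte(ssq(pert), base - 1e-12)
  }
})

test_that("corrected edges close every cycle and are antisymmetric", {
  net <- tri(2.5)
  ce <- corrected_edges(sfc_correct(net, reference = "a"), net)
  # cycle a->b->c->a
  cyc <- ce$ddG_corrected[1] + ce$ddG_corrected[2] - ce$ddG_corrected[3]
  expect_lt(abs(cyc), 1e-9)
  g <- structure(sfc_correct(net, reference = "a")$nodes$dG,
                 names = c("a", "b", "c"))
  expect_equal(g[["b"]] - g[["a"]], -(g[["a"]] - g[["b"]]))
  # consistent network: corrected equals input
  ce0 <- corrected_edges(sfc_correct(tri(2), reference = "a"), tri(2))
  expect_equal(ce0$ddG_corrected, ce0$ddG, tolerance = 1e-12)
})

test_that("gauge shift moves node values, not corrected edges", {
  net <- tri(2.5)
  a0 <- sfc_correct(net, reference = "a", anchor = 0)
  a5 <- sfc_correct(net, reference = "a", anchor = -5)
  expect_equal(a5$nodes$dG, a0$nodes$dG - 5)
  expect_equal(corrected_edges(a5, net)$ddG_corrected,
               corrected_edges(a0, net)$ddG_corrected)
  # reference change shifts by a constant too
  ab <- sfc_correct(net, reference = "b")
  shift <- ab$nodes$dG - a0$nodes$dG
  expect_equal(diff(range(shift)), 0, tolerance = 1e-10)
})

test_that("noise-free generated networks reproduce the truth up to anchor", {
  for (topo in c("star", "cycle", "dense")) {
    g <- gen_network(7, topo, sigma = 0, seed = 21)
    nfe <- sfc_correct(g$net, reference = "auto")
    got <- structure(nfe$nodes$dG, names = nfe$nodes$node)
    shift <- got[names(g$truth)] - g$truth
    expect_lt(diff(range(shift)), 1e-9)
    expect_lt(max(abs(nfe$residuals$residual)), 1e-9)
  }
})

test_that("star-topology residuals equal the noise draws in closed form", {
  # a star has no cycles: the least-squares fit is exact on every edge
  g <- gen_network(6, "star", sigma = 0.5, seed = 8)
  nfe <- sfc_correct(g$net, reference = "lig01")
  expect_lt(max(abs(nfe$residuals$residual)), 1e-10)
})

test_that("node recovery improves with edge redundancy", {
  rmse_for <- function(extra) {
    mean(vapply(1:50, function(s) {
      g <- gen_network(8, "cycle", sigma = 0.5, seed = s,
                       extra_chords = extra)
      nfe <- sfc_correct(g$net, reference = "lig01")
      got <- structure(nfe$nodes$dG, names = nfe$nodes$node)
      resid <- got[names(g$truth)] - g$truth
      resid <- resid - mean(resid)
      sqrt(mean(resid^2))
    }, numeric(1)))
  }
  r0 <- rmse_for(0); r8 <- rmse_for(8); r16 <- rmse_for(16)
  expect_lt(r8, r0)
  expect_lt(r16, r8)
})

test_that("disconnected networks and bad references error", {
  net <- perturbation_network(data.frame(from = c("a", "c"), to = c("b", "d"),
                                         ddG = c(1, 1)))
  expect_error(sfc_correct(net, reference = "a"), "disconnected")
  expect_error(sfc_correct(tri(2), reference = "zz"), "reference")
  expect_error(perturbation_network(data.frame(from = "a", to = "a", ddG = 0)),
               "self-edge")
})

test_that("inverse-variance weighting pulls the fit toward precise edges", {
  edges <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                      ddG = c(1, 1, 2.5), sem = c(0.01, 0.01, 1))
  net <- perturbation_network(edges)
  w <- sfc_correct(net, reference = "a", weighted = TRUE)
  u <- sfc_correct(net, reference = "a", weighted = FALSE)
  # weighted solution honours the two precise edges almost exactly
  g <- structure(w$nodes$dG, names = w$nodes$node)
  expect_lt(abs((g[["b"]] - g[["a"]]) - 1), 0.01)
  expect_lt(abs((g[["c"]] - g[["b"]]) - 1), 0.01)
  expect_gt(abs(structure(u$nodes$dG, names = u$nodes$node)[["b"]] - 1), 0.05)
})

test_that("experimental anchoring matches means over common nodes", {
  g <- gen_network(5, "dense", sigma = 0, seed = 3)
  net <- perturbation_network(g$net$edges, experimental = g$truth)
  nfe <- sfc_correct(net, reference = "auto", anchor = "experimental")
  got <- structure(nfe$nodes$dG, names = nfe$nodes$node)
  expect_equal(mean(got[names(g$truth)]), mean(g$truth), tolerance = 1e-9)
  expect_equal(got[names(g$truth)], g$truth, tolerance = 1e-9)
})

test_that("network CSV I/O round-trips edges and node results", {
  dir <- withr::local_tempdir()
  g <- gen_network(5, "cycle", sigma = 0.2, seed = 2)
  epath <- file.path(dir, "edges.csv")
  write.table(data.frame(ligA = g$net$edges$from, ligB = g$net$edges$to,
                         ddG = g$net$edges$ddG, sem = g$net$edges$sem),
              epath, sep = ",", row.names = FALSE, quote = FALSE)
  net <- read_network(epath)
  expect_equal(net$edges$ddG, g$net$edges$ddG)
  nfe <- sfc_correct(net, reference = "auto")
  npath <- file.path(dir, "nodes.csv")
  write_node_energies(nfe, npath)
  back <- read.table(npath, header = TRUE, sep = ",")
  expect_equal(back$ligand, nfe$nodes$node)
  expect_equal(back$dG, nfe$nodes$dG, tolerance = 1e-12)
  expect_true(all(c("n_edges", "max_residual") %in% names(back)))
})
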