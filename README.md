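# rbfekit

Setup and analysis toolkit for dual-topology **relative binding free
energy (RBFE)** calculations run under **spherical boundary conditions
(SBC)**.

RBFE workflows estimate ΔΔG_bind — the difference in binding free energy
between two congeneric ligands against one target — by alchemically
transforming ligand A into ligand B along a ladder of coupling values λ,
once in the solvated binding site (*protein leg*) and once in bulk water
(*water leg*):

    ΔΔG_bind = ΔG_protein − ΔG_water

In a *dual topology* both end-state ligands coexist in the simulation;
cross-topology distance restraints between chemically equivalent heavy
atoms keep the two topologies superposed so they sample the same pose.
rbfekit implements everything upstream and downstream of the MD engine:

* **Atom mapping** — minimum-cost Cartesian-overlap assignment between
  heavy atoms of two aligned ligands (Hungarian algorithm, 0.95 Å default
  cutoff), with ring-break / ring-size / whole-rings sanity filters and a
  same-net-charge gate.
* **Restraint generation** — a hierarchical equivalence criterion decides
  which mapped pairs are restrained: an atom-comparison method
  (`element`, `hybridization`, `aromaticity`, `heavyatom`) combined with
  a ring-substituent strictness level (`_p` permissive, `_ls` less
  strict, `_s` strict), e.g. `heavyatom_p` (the default). Emitted
  restraints carry k = 0.5 kcal mol⁻¹ Å⁻², activated beyond 0.1 Å.
* **Sphere setup** — 25 Å droplet centred on the ligands, per-atom
  boundary constraints (200 kcal mol⁻¹ Å⁻²) outside the radius, lattice
  solvation with 3.0 Å clearance, per-edge removal of waters clashing
  with either end-state ligand, dual-topology merge.
* **λ scheduling & input emission** — 101 sigmoidally distributed windows
  (λ_k = ½(1 + tanh(s·x_k)/tanh s), densest at the end states), two legs
  proceeding independently from the shared midpoint 0.5; 10 replicates
  per leg with derived seeds; deterministic plain-text window manifests.
* **BAR analysis** — Bennett acceptance ratio per adjacent window pair
  (self-consistent solution to 1e-8 kcal/mol, asymptotic variance as a
  diagnostic), first-100-step equilibration discard, per-leg summation,
  replicate means ± SEM as the headline uncertainty, thermodynamic-cycle
  combination.
* **Cycle-closure correction (SFC)** — absolute per-ligand ΔG by global
  least squares against the pairwise edges, anchored at the most
  connected ligand; corrected edges close every cycle to machine
  precision.
* **Benchmark metrics** — Kendall τ_b, MUE/RMSE, percentile-bootstrap 95%
  CIs (1000 resamples), directional Mann–Whitney U tests with Holm
  correction.
* **Synthetic fixtures** — toy ligand pairs with hand-derived restraint
  truths, Gaussian-Crooks work samples with analytic ΔG, networks with
  known node values: the whole pipeline runs and is tested without any
  external data.

## Worked example

```r
library(rbfekit)

## 1. map benzene -> toluene and generate restraints
ligA <- fixture_molecule("benzene"); ligB <- fixture_molecule("toluene")
mp <- filter_mapping(map_by_distance(ligA, ligB, cutoff = 0.95), ligA, ligB)
mp
#> <atom_mapping> 6 pair(s), source: distance
rs <- set_restraints(ligA, ligB, mp, "heavyatom_ls")
rs
#> <restraint_set> 5 restraint(s) [heavyatom_ls], 1 mapped pair(s) excluded
```

All six ring atoms map (the methyl carbon has no partner within 0.95 Å);
under `less_strict` the substituted ring position is excluded — one side
bare, one side methyl — leaving 5 restraints, each with k = 0.5 and
activation 0.1 Å.

```r
## 2. build the droplet system
dual <- build_dual_topology(ligA, ligB, rs)
sys <- solvate_sphere(sphere_system(sphere_center(ligA, ligB), 25, coords(ligA)))
sys <- remove_clashing_waters(sys, dual)
sys
#> <sphere_system> r = 25 A at (0.22, 0.00, 0.00); 6 solute atom(s)
#>   (0 boundary-constrained), 2102 water(s)

## 3. analyze a synthetic edge with known ddG = -2.4 - (-1.1) = -1.3
edge_dir <- tempfile()
gen_edge_data(edge_dir, dG_protein = -2.4, dG_water = -1.1, sigma = 1,
              n_windows = 5, n_samples = 600, replicates = 5, seed = 42)
analyze_edge(edge_dir, discard = 100)
#> <edge_result> ddG_bind = -1.241 +/- 0.047 kcal/mol
#>   (protein -2.364 +/- 0.017, water -1.123 +/- 0.044)
```

The planted −1.3 kcal/mol is recovered within sampling noise (5 replicates
per leg, 5 windows × 500 production samples after the 100-sample discard).

```r
## 4. cycle-closure correction and benchmark metrics
g <- gen_network(8, "dense", sigma = 0.4, seed = 42)
nfe <- sfc_correct(g$net, reference = "auto")
nfe
#> <node_free_energies> 8 node(s), reference lig01, max |edge residual| 0.729 kcal/mol
pred <- structure(nfe$nodes$dG, names = nfe$nodes$node)
pred <- pred - mean(pred) + mean(g$truth)        # gauge-match to the truth scale
benchmark_metrics(pred[names(g$truth)], g$truth, seed = 1)
#>   metric     value     ci_low   ci_high n
#> 1    tau 1.0000000 1.00000000 1.0000000 8
#> 2    mue 0.1602708 0.07429389 0.2552295 8
```

With 0.4 kcal/mol edge noise on a dense 8-ligand network the correction
recovers the true ranking perfectly (τ_b = 1) and the node values to
0.16 kcal/mol MUE — the redundancy of a dense network averages the edge
noise down.

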