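---
title: "Methods: dual-topology RBFE setup and analysis under spherical boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-topology RBFE setup and analysis under spherical boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfekit)
```

# Scope and model

rbfekit implements the computational stages that surround a molecular
dynamics engine in a relative binding free energy (RBFE) workflow run under
spherical boundary conditions (SBC). The physical picture: two congeneric
ligands A and B are transformed into one another alchemically, once in the
solvated binding site (the *protein leg*) and once in bulk water (the
*water leg*). Both legs are sampled over a ladder of coupling values
$\lambda \in [0, 1]$ in a *dual topology*: the atoms of both end-state
ligands coexist, their nonbonded interactions scaled complementarily, and
cross-topology distance restraints keep chemically equivalent heavy atoms
superposed so the two topologies sample the same pose. The thermodynamic
cycle then gives

$$\Delta\Delta G_\mathrm{bind} = \Delta G_\mathrm{protein} - \Delta G_\mathrm{water}.$$

The MD engine itself (integrator, surface-constrained water model,
local-reaction-field electrostatics, force-field parameterisation) is out
of scope; rbfekit prepares everything the engine needs and analyses
everything it produces, and ships synthetic generators so the entire
pipeline is testable with no external data.

# Molecular model and perception

Molecules are atom/bond graphs with 3D coordinates, formal charges, and
perceived ring membership, aromaticity and hybridization. Internal atom
indices are 1-based (the natural R convention; a 0-based convention inside
R code invites silent off-by-one subscript bugs), while all serialized
interchange formats — the mapping TSV and the restraint TSV — use 0-based
indices, converted only at the I/O boundary.

Rings are the smallest set of smallest rings (SSSR), built from per-bond
shortest cycles and a greedy size-ordered selection up to the cyclomatic
number; the suite checks it against an exhaustive simple-cycle GF(2) basis
on every fixture molecule.

Aromaticity uses a fixed heuristic perception model, applied identically
throughout a run: a ring is aromatic iff all of its bonds carry the SDF
aromatic bond order (4), *or* its size is 5 or 6 and every ring atom is
$\pi$-capable (participates in a double/triple/aromatic bond, or is N, O or
S contributing a lone pair). Hybridization follows bond orders: a triple
bond or two doubles gives sp, any double or aromatic bond sp2, otherwise
sp3. This is deliberately simple — no Hückel electron counting — and is
documented here precisely because restraint configurations that compare
aromaticity or hybridization inherit its definitions. On the idealized
fixture chemistry (benzenoid rings, Kekulé or aromatic bond blocks) it
agrees with standard perception; exotic systems (azulenes, fulvenes,
charged rings) may be classified differently than an electron-counting
perceiver would.

Hydrogens are retained in records but ignored by mapping and restraints:
all pairing logic is heavy-atom only, and passing a hydrogen to an
equivalence check is a contract violation. PDB input keeps the first model
and first alternate location (noted by message); waters are recognised by
residue name (HOH/WAT/SPC/T3P).

# Atom mapping

`map_by_distance()` computes the minimum-total-distance one-to-one
assignment over heavy-atom pairs within a Cartesian cutoff, solved exactly
with the Hungarian algorithm ($O(n^3)$, potentials formulation) — no
package on the system provides a weighted assignment solver, so it is
implemented here and tested against brute-force permutation enumeration.
Determinism matters for reproducible edge setup: cost ties are broken
toward the lowest (index in A, index in B) by an index-derived epsilon that
is orders of magnitude below any physical distance difference.

The default cutoff is 0.95 Å, the convention of Cartesian-overlap mappers
for congeneric series; it is a parameter, not a constant. Element identity
is *not* required at mapping time — chemistry is judged later by the
filters and the restraint criteria.

Three sanity filters then remove unreasonable correspondences, each
operating pair-by-pair (a failed ring check removes the offending pairs,
not the whole mapping — users who want all-or-nothing semantics can test
`n_pairs()` before and after):

* **ring-break** — drops pairs where exactly one partner is a ring atom;
* **ring-size** — drops pairs whose smallest containing rings differ in
  size (a fused-ring atom is judged by its *smallest* ring);
* **whole-rings-only** — a ring atom's pair survives only if every atom of
  the rings it belongs to is mapped to ring partners; partially mapped
  rings are dismantled atom-by-atom.

The filters are idempotent, and on the fixture set order-invariant; both
properties are asserted in the suite. Transformations are additionally
gated on equal net formal charge (`validate_same_charge()`): changing the
net charge inside a finite droplet changes the long-range electrostatics
between end states. A manual mapping path (`read_mapping()` on the same
two-column TSV) covers series where the automatic overlay is chemically
wrong.

# Restraint generation

`set_restraints()` decides which mapped heavy-atom pairs receive
cross-topology distance restraints. The decision is hierarchical:

1. **Ring correspondence.** Ring $r_A$ corresponds to $r_B$ when strictly
   more than half of the smaller ring's atoms are mapped between them
   (majority rule; each ring enters at most one correspondence, best
   overlap first). An exact-half overlap is *not* a majority.
2. **Atom comparison**, one of `element`, `hybridization`, `aromaticity`,
   `heavyatom` (any heavy atom matches any heavy atom).
3. **Substituent strictness** at mapped ring positions in corresponding
   rings: `permissive` compares ring atoms only; `less_strict` requires
   both positions to agree on the *presence* of heavy-atom substituents
   (element ignored); `strict` additionally requires the first substituent
   atoms to match by element.

A mapped ring pair is restrained iff it passes both the atom comparison
and the strictness check; a mapped acyclic pair is judged by atom
comparison alone — strictness is a ring-substituent concept and extending
it off-ring has no defensible reading, so acyclic positions deliberately
get atom-level equivalence only. A substituent is the first heavy atom
bonded to the ring atom outside any ring; branched substituents are
compared by that first atom only (comparing whole subtrees would make
`strict` reject benign homologations such as ethyl vs. propyl). Both
choices are design decisions of this package and are stated here because
other implementations could reasonably differ.

Every emitted restraint carries a force constant of 0.5 kcal mol⁻¹ Å⁻²
activated when the pair distance exceeds 0.1 Å — soft enough not to bias
sampling, firm enough to hold the topologies in phase. Unmapped atoms are
never restrained; that is the mechanism by which structurally dissimilar
R-groups lying far apart in space (the hardest transformation class)
correctly receive *no* positional coupling under every configuration, as
the `syk_mimic` fixture asserts. The default configuration is
`heavyatom_p`, the permissive all-heavy-atoms setting that behaves
sensibly across most congeneric series; stricter settings are for series
where substituent chemistry must match before coupling positions.

Useful structural guarantees, all property-tested: strictness and method
inclusions are monotone (`strict` ⊆ `less_strict` ⊆ `permissive`, and
`element` ⊆ `heavyatom`), output transposes exactly under A↔B relabeling,
and the excluded-pair log records which rule removed every mapped pair
that did not become a restraint.

# Sphere system construction

The droplet is centred on the unweighted heavy-atom centroid of the union
of both end-state ligands (they can differ in extent; the union keeps both
inside), radius 25 Å by default. Solute atoms farther than the radius from
the centre are harmonically constrained at 200 kcal mol⁻¹ Å⁻², per atom
(never per residue); hydrogens inherit their parent's class at write-out.

Solvation places water oxygens on a cubic lattice of spacing 3.107 Å
(bulk-water number density, $\rho \approx 0.0334$ Å⁻³) anchored at the
sphere centre and clipped to the radius, then removes any water closer
than 3.0 Å to a solute heavy atom. A lattice rather than a pre-equilibrated
droplet snapshot keeps the generator deterministic and dependency-free;
the engine's own equilibration relaxes the lattice, and a pre-built
droplet can be substituted by writing the `waters` matrix directly.
Waters clashing with *either* end-state ligand of the merged dual topology
are removed per edge (cutoff defaulting to the same 3.0 Å clearance).
Surface-water restraint physics belongs to the engine and is not modelled.

The dual topology concatenates A's atoms then B's (B offset by $|A|$),
with complementary presence masks and restraint indices re-expressed in
merged numbering; no bonds cross the A/B boundary and both ligands keep
their input coordinates.

# The λ schedule and protocol

Windows follow a sigmoidal spacing

$$\lambda_k = \tfrac12\left(1 + \frac{\tanh(s\,x_k)}{\tanh(s)}\right),
\qquad x_k \ \text{uniform on } [-1, 1],$$

with steepness $s = 2$ by default, 101 windows, exact endpoints 0 and 1
and exact midpoint 0.5 (symmetry is enforced against floating-point
rounding). The derivative of the map is largest at the midpoint, so
windows are densest near the end states where phase-space overlap between
adjacent windows is poorest — the usual motivation for sigmoidal ladders.
Any strictly monotone sigmoid with these invariants would serve; the tanh
form is pinned for reproducibility and exposed via `steepness`. Both legs
start from the shared midpoint and proceed independently toward their end
state, each leg re-listing $\lambda = 0.5$.

The default protocol samples 5000 steps of 2 fs per window (10 ps), giving
$101 \times 10 = 1010$ ps of production per replicate leg, with 10
replicates per leg (20 replicate directories per edge) and the first 100
steps of each window discarded at analysis time. Replicate seeds derive
deterministically from one master seed without touching the caller's RNG
state. Window manifests are a versioned plain-text dialect of this package
(engine-input bit-compatibility is a non-goal); re-emission is
byte-identical, which the suite asserts, because reproducible file trees
are what make edge provenance auditable. Equilibration emission is a stub
(`equilibration_steps 0`) — pre-production equilibration schedules are
engine policy, not analysis policy.

# BAR analysis

For each adjacent window pair, with reduced works $w_F = \beta\,\Delta U_F$
sampled in the lower window and $w_R = \beta\,\Delta U_R$ in the upper, and
$M = \ln(n_F/n_R)$, the Bennett acceptance ratio estimate solves

$$\sum_F f(M + w_F - \Delta f) \;=\; \sum_R f(-M + w_R + \Delta f),
\qquad f(x) = \frac{1}{1 + e^{x}}.$$

The left side is increasing and the right decreasing in $\Delta f$, so the
root is unique; it is bracketed by the two one-sided exponential-averaging
(EXP) estimates (expanded if necessary) and found by Brent's method to
1e-8 kcal/mol. The reported per-window uncertainty is the standard
asymptotic variance from the relative fluctuations of the Fermi weights.
A window where the mean Fermi weight of either direction underflows is
flagged `overlap_warning` — the estimate is returned but should not be
trusted, and more windows (not more samples) are the fix.

One empirical note: on Gaussian work fixtures the *population* values of
forward EXP, reverse EXP and BAR coincide, so the textbook statement that
BAR lies between the two EXP estimates holds in expectation (each EXP is
biased one-sidedly by Jensen's inequality) but not sample-exactly; the
suite asserts the bracketing within the BAR standard error.

Temperature enters only through $\beta$; it is not recorded in the energy
files, so the default 298.15 K is a configurable analysis parameter. All
energies are kcal/mol throughout.

Window estimates are summed per leg (variances in quadrature; a missing
window pair is an error naming the gap). Replicates are aggregated as the
mean of per-replicate leg totals with SEM $= s/\sqrt{n}$ — replicate
scatter, not the per-window asymptotic variance, is the headline
uncertainty, because replicate-to-replicate variation includes the
sampling variability that the asymptotic formula underestimates; the BAR
variance is kept as a per-window diagnostic. The two legs combine as
$\Delta\Delta G = \Delta G_\mathrm{protein} - \Delta G_\mathrm{water}$ with
SEMs in quadrature.

# Cycle-closure correction (SFC)

Free energy is a state function: around any closed cycle of the
perturbation network the edge values must sum to zero, and raw estimates
never quite do. Rather than enumerating cycles, the state-function
correction assigns each ligand an absolute value $g_i$ and solves

$$\min_g \sum_{(i \to j)} w_{ij}\,(g_j - g_i - \Delta\Delta G_{ij})^2$$

on the edge–node incidence system (QR; Moore–Penrose pseudo-inverse with a
warning if the reduced system is rank-deficient), anchored at the most
connected ligand (maximum degree, ties lexicographic). Corrected edges
$g_j - g_i$ then close every cycle to machine precision and are exactly
antisymmetric. Edges are unweighted by default — per-edge SEMs from small
replicate counts are themselves noisy, and weighting by them can
overcommit to lucky edges — with inverse-variance weighting
(`weighted = TRUE`) available. The gauge is $g_\mathrm{ref} = 0$ by
default; `anchor = "experimental"` instead shifts so the mean predicted
$\Delta G$ matches the mean experimental value over nodes with data, the
convention used when comparing absolute values to experiment. Disconnected
networks are an error listing the components: assigning values across
components would invent unmeasurable offsets.

# Benchmark metrics

Kendall's rank correlation is the tie-corrected $\tau_b$ (experimental
affinities contain ties; the uncorrected variants understate concordance
there), delegated to `stats::cor` and oracle-checked against explicit pair
enumeration. MUE and RMSE follow their definitions (RMSE ≥ MUE always, by
Jensen). Confidence intervals are percentile bootstrap over paired
(predicted, experimental) resamples, 1000 resamples by default —
percentile rather than BCa keeps the interval definition transparent at
these sample sizes, at the cost of the slight undercoverage the suite's
coverage test brackets (88–99% nominal band for the 95% interval).
Significance testing runs both one-sided Mann–Whitney U tests per
comparison (exact where `stats::wilcox.test` can be, normal approximation
with tie correction otherwise), reports the better-supported direction,
and Holm-adjusts the chosen one-sided p-values across all comparisons —
"two directional tests" is read as two one-sided tests with the direction
reported, the reading that preserves directional conclusions after
correction.

# Synthetic generators: what they do and do not show

The fixture generators are first-class, tested code, and all package-level
evidence rests on them:

* `toy_ligand_pairs()` — idealized geometries (flat rings, standard bond
  lengths) with *hand-derived* expected mappings and restraint sets for
  all 12 configurations. They exercise the decision space (heteroatom
  swap, ring-size change, R-group growth, distant R-groups, partial ring
  overlap), not conformational realism: no torsional strain, no poor
  poses, no protonation ambiguity.
* `gen_work_samples()` / `gen_bar_samples()` — Gaussian forward/reverse
  work obeying the Crooks fluctuation relation for Gaussian work
  (means $\pm\Delta G + \beta\sigma^2/2$, shared $\sigma$), a standard
  closed-form construction that provides an analytic truth independent of
  the BAR implementation, plus a decaying-bias head so the equilibration
  discard is actually load-bearing in tests. Real work distributions are
  not Gaussian and can be multimodal; recovery on these fixtures
  demonstrates estimator correctness, not MD convergence.
* `gen_network()` — node truths plus Gaussian edge noise over star, cycle
  and dense topologies; star networks have no cycles, so their residuals
  vanish in closed form, a sharp oracle for the least-squares path.
* `toy_sphere_system()` — points at controlled radii with stored
  classification truth.

Passing tests therefore show the algorithms are implemented correctly
under their stated assumptions; they say nothing about force-field
accuracy, sampling convergence, or pose quality of real systems.

# Numerical choices and problem sizes

Tolerances: BAR root 1e-8 kcal/mol; SFC recovery and cycle closure
asserted at 1e-9; oracle equality at 1e-10–1e-12. Assignment ties broken
by index; `which.max` ties in reference selection resolve
lexicographically because node levels are sorted. Degenerate inputs:
empty mappings warn and propagate as empty restraint sets; all-tied
Kendall inputs are NA with a warning; single replicates report a mean with
missing SEM; zero-overlap BAR warns and flags.

The suite runs at deliberately small scale — 300–5000 work samples per
window, networks of 5–8 nodes, 50–200 simulation repeats per statistical
assertion, 200 bootstrap-coverage draws — sizes chosen so every
distributional claim still has power while the whole suite completes in
well under a minute. The acceptance script re-derives its quantities at
the same scales from a single command-line seed.

# Known limitations

* Aromaticity/hybridization perception is heuristic (above); restraint
  configurations comparing them inherit its edge cases.
* A substituent that is itself part of another ring (biaryl links) is not
  counted as a substituent by the strictness check — the first heavy
  neighbour *outside any ring* is compared.
* SFC reports no per-node uncertainty; error propagation through the
  pseudo-inverse is future work.
* The water lattice is unequilibrated by construction; densities at the
  droplet surface are approximate until the engine relaxes them.
* `analyze_edge()` expects this package's two-column energy format; native
  engine energy dialects need a converter upstream.
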