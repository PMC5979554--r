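---
title: "Methods: the hybrid ABC/DE docking search and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid ABC/DE docking search and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivedock)
```

## The docking problem

`hivedock` performs re-docking of a flexible ligand into a rigid receptor:
given both molecules in AutoDock's PDBQT dialect and a search box around the
binding site, it searches for the ligand conformation with the lowest
estimated binding free energy. A conformation (genotype) has `7 + T` genes:
a translation of the ligand's rigid-root centroid relative to the box center
(3 genes, Angstrom), a quaternion orientation (4 genes, renormalised on
use), and one angle per rotatable bond (`T` genes, radians, wrapped to
`(-pi, pi]`). The phenotype is built by applying torsions branch by branch
down the ligand's torsion tree (parents before children), then rotating the
whole ligand about its root centroid and translating it into the box.

## The scoring function

Poses are scored by a semi-empirical pairwise free-energy model,

$$\Delta G = (V^{L-L}_{bound} - V^{L-L}_{unbound})
           + (V^{P-P}_{bound} - V^{P-P}_{unbound})
           + (V^{P-L}_{bound} - V^{P-L}_{unbound} + \Delta S_{conf}),$$

where each pairwise term $V$ sums dispersion/repulsion (12-6), hydrogen
bonding (12-10 on donor-acceptor pairs), screened electrostatics and
Gaussian desolvation over atom pairs:

$$V = W_{vdw}\sum_{ij}\Big(\frac{A_{ij}}{r^{12}}-\frac{B_{ij}}{r^{6}}\Big)
    + W_{hb}\sum_{ij}E(t)\Big(\frac{C_{ij}}{r^{12}}-\frac{D_{ij}}{r^{10}}\Big)
    + W_{el}\sum_{ij}\frac{q_iq_j}{e(r)\,r}
    + W_{sol}\sum_{ij}(S_iV_j+S_jV_i)\,e^{-r^2/2\sigma^2}.$$

Choices the model text leaves open were resolved as follows and are
configurable through `load_forcefield()`:

* **Constants.** The per-type radii, well depths, solvation parameters and
  volumes, the term weights (0.1662, 0.1209, 0.1406, 0.1322, 0.2983), the
  desolvation width $\sigma = 3.5$ A and the charge-dependent solvation
  increment $0.01097\,|q|$ are the published AutoDock 4.2 free-energy-model
  defaults, shipped as a plain-text table (`inst/extdata/ad4_types.txt`) so
  users can substitute their own.
* **Dielectric $e(r)$.** The Mehler-Solmajer sigmoidal screening function,
  as used by AutoDock 4; a constant dielectric is available and keeps hand
  checks simple.
* **H-bond directionality $E(t)$.** Taken as 1 (distance-only 12-10 well):
  inferring donor geometry needs bonded hydrogens' parents, which PDBQT
  does not always carry. Donor-acceptor pairs (HD against OA/NA/SA) use the
  12-10 well *instead of* the 12-6 term, with the acceptor's equilibrium
  distance and depth.
* **Entropy.** $\Delta S_{conf} = W_{conf} \times T$, the torsion count.
* **Unbound reference.** The input-file conformation: the internal-energy
  contribution is the strain of the docked pose relative to the file pose.
  The rigid receptor's P-P difference is identically zero, and the unbound
  P-L term is zero (infinite separation).
* **Ligand internal energy.** Summed over "moving pairs": atom pairs in
  different rigid groups more than three bonds apart. Bonds are inferred
  from the reference coordinates by a covalent distance cutoff (1.9 A;
  2.42 A around sulfur) because PDBQT carries no connectivity records.
* **No cutoff, no smoothing.** Sums run over all pairs by default, which
  keeps the implementation exactly equal to a naive double-loop oracle; an
  8 A cutoff is available for speed.

Energies are evaluated directly over receptor-ligand atom pairs rather than
through precomputed affinity grids; for the problem sizes this package
targets the exact sums are fast and keep the scoring path testable against
brute force.

## The search: ABC + DE under an adaptive partition

Two population metaheuristics evolve one shared population of genotypes:

* **Artificial bee colony (ABC).** Half of a subpopulation are food
  sources. Employed bees probe `v = x_i + phi (x_i - x_k)` with
  `phi ~ U(-1, 1)` against a random other food source; onlooker bees repeat
  this for food sources drawn with fitness-proportional probability;
  greedy one-to-one selection keeps the better of candidate and incumbent
  (ties go to the candidate). A food source that fails to improve more than
  `limit = 100` times is abandoned: at most one such source per generation
  (the worst) is replaced by a fresh random genotype (the single scout).
  Because raw binding energies are negative, onlooker probabilities use the
  standard ABC fitness transform `F = 1/(1+E)` for `E >= 0`, else
  `1 + |E|`, which is strictly anti-monotone in energy.
* **Differential evolution (DE), rand/1/bin.** For each target, three
  distinct random donors form the mutant `v = x_{r1} + F (x_{r2} - x_{r3})`
  with `F = 0.9`; binomial crossover with `CR = 0.8` mixes mutant and
  target. One uniformly chosen gene is always taken from the mutant — the
  standard `j_rand` device, adopted because plain binomial crossover can
  return the target unchanged and stall the search. Survival is one-to-one
  greedy with ties to the trial.

Both engines operate on the raw `7 + T` gene vector, quaternion components
included, followed by a repair step (clamp translations to the box,
renormalise the quaternion, wrap torsions). The search budget is counted in
score-function evaluations (default 27,000 with a population of 100,
matching the reference parameterisation; "iterations" in the original
description are read as evaluations, configurable either way through
`dock_control()`).

**The adaptive population partition (APP).** Each generation the population
is shuffled and split: a fraction `PR` (initially 0.5) goes to ABC, the
rest to DE. After both engines run, the subpopulations merge and `PR` is
updated from two signals per engine `z`:

* the *elite probability* `O_z`: the fraction of the global top-20%
  individuals that reside in subpopulation `z`, and
* the *evolution rate* `v_z`: the slot-paired relative energy improvement
  `sum((before - after)/(|after| + eps))`, floored at a small positive
  constant. Under minimisation of negative energies the raw
  improvement-difference sum would carry the wrong sign for the update
  rule, so the rate is defined with "improvement positive"; the floor
  keeps the update well defined.

The update is `PR = O1 v1 / (O1 v1 + O2 v2)`, clamped to `[0.1, 0.9]`, with
two guards: a zero denominator falls back to 0.5, and a generation in which
*neither* engine improved (both rates at the floor) resets `PR` to 0.5
rather than letting the elite counts alone dictate the split — with no
improvement signal the elite distribution carries no information about
search capability. Subpopulations never shrink below 4 individuals (DE's
minimum), and `M1 = round(M * PR)` rounds half away from zero.

Baselines `"abc"`, `"de"` (whole population under one engine) and
`"random"` (best-of-budget i.i.d. sampling) share the same budget
accounting for fair comparison.

## Synthetic study systems

Real benchmark complexes require protein structures and preparation tools,
so the package generates its own study systems (`make_toy_complex()`),
scored through the production scoring path with no special-cased physics:

* The ligand is a zigzag chain (bond length ~1.55 A) with an aperiodic
  helical twist that makes it chiral — without the twist, end-to-end
  flipped poses are nearly congruent with the planted pose and become
  spurious near-degenerate optima. Ends carry a non-acceptor nitrogen
  (+0.45 e) and an acceptor oxygen (-0.45 e) with a linear charge gradient
  between them. Torsions form a nested chain of branches; the terminal
  branch owns two atoms so that every torsion moves at least one off-axis
  atom.
* The receptor pocket is moulded around the planted pose: each of the
  `n_rec = 60` receptor atoms is anchored to one ligand atom at exactly
  that pair's energy-optimal distance (12-6 minimum, or the 1.9 A 12-10
  minimum for donor-acceptor pairs), in a rejection-sampled direction that
  avoids clashing with the other ligand atoms and leaves an entry channel
  open towards +z. Receptor charges complement their anchor's charge.
  Hydrogen-bond donors are anchored alternately to the ligand's acceptor
  end, pinning the pose with steep 12-10 wells.
* The search box is a snug 7 A cube centered on the pocket, the usual
  practice of boxing the known active site.

The generator is deterministic given its seed and leaves the caller's RNG
stream untouched. Its planted pose is verified (in the test suite) to beat
100 random genotypes and to sit at the bottom of the translation-lattice
landscape. What these fixtures do *not* emulate: real protein surface
topography, solvent structure, charge assignment noise, ligand ring
systems and symmetric substructures (so index-matched RMSD is exact), and
the much higher dimensionality of real binding sites. Passing the suite
therefore demonstrates the correctness and search behaviour of the
machinery at desk scale, not chemical accuracy on real complexes.

The five-complex benchmark suite (`toy_suite()`) spans 0-4 rotatable bonds
with 6-8 ligand atoms. Benchmarks in the tests and the acceptance script
run it at the reference search settings — population 100, budget 27,000
evaluations per run — against a 0.5 A translation-grid oracle (~3,400
lattice points per complex); with the compiled scoring core a full
three-algorithm, ten-seed comparison remains a desk-scale computation.
Population size matters here beyond speed: with small populations
(e.g. 40) the greedy one-to-one selection of both engines lets whichever
basin is sampled best at initialisation capture the whole population, and
runs intermittently finish in decoy basins; at population 100 the initial
sample covers the orientation space well enough that the planted funnel
wins reliably.

## Evaluation statistics

Following standard re-docking practice, a run is *successful* when the
heavy-atom, index-matched RMSD between the docked and the reference pose is
strictly below 2.0 A (no superposition, no symmetry correction — the toy
ligands have no automorphisms, and this is the simplest reproducible
convention; it is flagged in the documentation because symmetric real
ligands would need a correction). Box-plot summaries use type-7
(linear-interpolation) quantiles and Tukey 1.5 IQR whiskers. Algorithm
pairs are compared with a two-sided Mann-Whitney rank-sum test at
`alpha = 0.05` on n = 10 best values per algorithm — the test is a
deliberate choice: the evaluation protocol this follows names only "the
hypothesis test", and the rank-sum test is the field's default for
non-normal energy samples; fully tied samples return `p = 1`.

## Numerical choices and degenerate inputs

* Torsion wrap boundary: `(-pi, pi]`, ties at the boundary map to `+pi`.
* Quaternion repair: a numerically zero quaternion after evolver
  arithmetic resets to the identity orientation; `normalize_orientation()`
  on an exactly zero quaternion is an error.
* Pair distances are floored at 0.01 A inside the scorer so coincident
  atoms produce huge but finite repulsion; `pair_energy()` itself errors
  at `r = 0`.
* Elite ties are broken by stable population order; `E = round(0.2 M)` and
  `M1 = round(M PR)` round half away from zero.
* Rigid ligands (`T = 0`) have zero internal energy and zero entropy
  penalty by construction.
* With a fixed `seed`, `dock()` is bit-reproducible including its full
  convergence and partition trace.

## Known limitations

* Receptor flexibility, explicit water, and grid-map interpolation are out
  of scope; scoring is exact pairwise summation.
* `E(t) = 1` ignores hydrogen-bond directionality.
* Index-matched RMSD over-penalises symmetric ligands.
* The evaluation-budget reading of "iterations" halves-to-doubles the
  search effort relative to a generation-count reading; both are exposed
  through `dock_control()`.
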