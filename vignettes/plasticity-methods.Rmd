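---
title: "Quantifying and localizing surface plasticity of conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and localizing surface plasticity of conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastens)
```

## The problem

When an antibody matures against an antigen, its binding loops — above all
the CDR-H3 loop — tend to rigidify: the conformational ensemble narrows, and
the molecular surface it presents becomes less variable. `plastens`
quantifies this contrast between two ensembles of the same (or a mutated)
protein. It combines conventional flexibility metrics (cluster counts of a
pairwise-RMSD clustering, 2D-RMSD, RMSF/B-factors) with a voxel-based
*surface plasticity* measure that not only scores overall variability but
localizes it on the structure, plus a small tICA/Markov-state-model stack
for the kinetics of the loop.

## The plasticity model

All frames of an ensemble are first superposed on a stable reference
selection (by default the scaffold Cα atoms, i.e. the complement of the
analysed loop, so that loop motion is not absorbed into the fit). The
aligned ensemble is voxelized on an axis-aligned isotropic lattice: voxel
$v$ is *occupied* in frame $f$ iff its center lies within
$r_\mathrm{vdW} + r_\mathrm{probe}$ of any selected (by default heavy) atom.
Occupancy is deliberately binary; with $p_v$ the per-voxel occupancy
probability over $F$ frames, the population standard deviation is then
exactly

$$\sigma_v = \sqrt{p_v\,(1 - p_v)},$$

which has two useful consequences. First, the interpretation is direct:
voxels that are sometimes inside the protein and sometimes solvent-exposed
($p_v \approx 0.5$) carry the maximum SD of $0.5$ — these are the plastic
regions — while permanently buried or permanently empty voxels score 0.
Second, the closed form is a free correctness oracle: the test suite checks
the identity voxelwise to $10^{-12}$.

Raw SD grids are noisy — even rigid regions produce isolated
partially-occupied voxels at the surface. Both the mean and the SD grid are
therefore smoothed with a separable 3-D Gaussian (default $\sigma = 1.5$ Å,
kernel truncated at $4\sigma$, unit-sum, reflect padding), which preserves
total grid mass as long as the occupied volume stays away from the grid
boundary; `make_grid_spec()` guarantees that by inflating the bounding box
by the padding (default 4 Å) plus the largest van der Waals radius.

Two scalars summarize a smoothed SD grid:

* **global plasticity** — the volume-weighted integral
  $\sum_{v:\ \sigma_v > \theta} \sigma_v\, h^3$ (Å³) over supra-threshold
  voxels (spacing $h$, threshold $\theta = 0.05$ by default), and
* **localized plasticity** — the same integral partitioned over residues by
  assigning each supra-threshold voxel to the residue of its nearest heavy
  atom in the *mean* structure (within 4 Å; farther voxels are pooled as
  "unassigned"). The partition is conservative by construction: per-residue
  scores plus the unassigned remainder reproduce the global integral
  exactly, and the profile can be written into the B-factor column of a PDB
  file for colour-coding in a viewer.

For a two-ensemble comparison, `pair_align()` brings both ensembles into the
frame of the first ensemble's mean structure over a shared selection before
a common grid is built, so the two SD grids can be subtracted voxelwise
(`plasticity_difference()`); positive values mark regions more plastic in
the first (naive) ensemble.

## Flexibility and kinetics around the core

*Clustering.* `average_linkage_cluster()` implements unweighted average
linkage (UPGMA, exact cross-pair mean) on a pairwise loop-Cα RMSD matrix
with distance-cutoff termination: merging stops before the first merge whose
linkage distance exceeds the cutoff (1.2 Å by default), so every pair of
final clusters has average distance above it. The surviving cluster count is
the flexibility metric; `cluster_count_sweep()` recomputes it across
cutoffs to check that a naive-vs-matured ordering is stable under the
cutoff choice. Ties break deterministically (lowest cluster-index pair), and
the partition is validated in the tests against both an exhaustive
re-implementation and `stats::hclust`.

*RMSF / B-factors.* RMSF is the per-atom root-mean-square deviation from the
mean position of a pre-aligned ensemble; B-factors use the isotropic
Debye–Waller relation $B = \tfrac{8\pi^2}{3}\,\mathrm{RMSF}^2$, the standard
crystallographic convention (the relation is asserted to $10^{-9}$ relative
in the tests).

*Torsions.* $\psi$ dihedrals (N–CA–C–N′, IUPAC sign via the atan2 form,
cross-checked against `bio3d::torsion.xyz`) are expanded into interleaved
$(\sin\psi, \cos\psi)$ features. `metadynamics_cv()` exposes the plain
linear combination of these features that an enhanced-sampling run would
bias; since no particular combination weights are canonical, the default is
all-ones, and the weights are user-suppliable. No biasing is performed.

*Kinetics.* `tica()` solves the symmetrized generalized eigenproblem
$C_{0\tau} v = \lambda C_{00} v$ with a $10^{-10}$ ridge on $C_{00}$
(directions with relative variance below $10^{-8}$ are dropped with a
warning); eigenvalues are bounded by 1 and invariant under time reversal.
Microstates come from k-means++-seeded Lloyd iterations (deterministic given
the seed; 150 states by default). `estimate_msm()` uses sliding-window
counts, restricts to the largest strongly connected component (reporting the
retained count fraction), and in reversible mode symmetrizes counts,
$(C + C^\top)/2$, before row normalization — detailed balance then holds by
construction and the stationary distribution is the normalized row sum.
This is an approximation to the full reversible maximum-likelihood
estimator; for the well-sampled chains the package targets the difference
is negligible, and the closed form keeps the estimator deterministic and
exactly testable. Coarse-graining is a *crisp* PCCA-style assignment —
seeded k-means on the dominant right eigenvectors — rather than the
membership-optimizing PCCA+; it reproduces block structure exactly in the
metastable regime and is flagged as simplified. `ck_test()` compares
$T(\tau)^\kappa$ against a fresh estimate at lag $\kappa\tau$ on the common
active set.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| grid spacing | 1.0 | Å | resolves atomic radii (1.2–1.8 Å) without excessive memory |
| grid padding | 4.0 | Å | keeps occupied volume off the boundary for mass-preserving smoothing |
| probe radius | 0 | Å | plain vdW occupancy; set ~1.4 Å to emulate a water probe |
| smoothing σ | 1.5 | Å | suppresses single-voxel noise, preserves loop-scale features |
| SD threshold | 0.05 | – | removes the near-zero background from the integral |
| attribution radius | 4.0 | Å | typical heavy-atom contact distance for surface voxels |
| cluster cutoff | 1.2 | Å | conventional loop-clustering cutoff; sweep for robustness |
| microstates | 150 | – | conventional MSM discretization for loop kinetics |
| MSM lag | user | frames | convert from time via the trajectory frame interval |

All of these are recorded in the JSON run report of `run_compare()`.

## The synthetic generator and what it does (not) show

`naive_matured_pair()` builds two ensembles over one toy topology: a
10-residue scaffold chain ("S") and a 6-residue loop chain ("H") of ideal
poly-alanine-like backbone geometry (3.8 Å Cα spacing). Both share scaffold
noise (σ 0.3 Å per axis); the "naive" loop fluctuates with σ 1.0 Å and
additionally hops between two conformations 3 Å apart via a symmetric
two-state Markov chain (switch probability 0.1 per frame), while the
"matured" loop fluctuates with σ 0.2 Å about one conformation. 150 frames
per ensemble keep every documented ordering (cluster counts, plasticity,
RMSF) decidable in seconds while leaving the contrast far from marginal.
Displacements are i.i.d. per frame except for the explicit two-state chain,
so every expectation is closed-form: loop RMSF $\sigma\sqrt{3}$, chain
stationary distribution $(\tfrac12, \tfrac12)$, second eigenvalue
$1 - 2\,p_\mathrm{switch}$, and half-occupancy (SD 0.5) voxels in the
state-displacement region.

What the generator does *not* emulate: temporal correlation of thermal
noise, side chains, solvent, anisotropic or correlated loop modes, and the
microsecond free-energy landscapes of real antibody fragments. Passing
tests therefore demonstrate correctness of the *procedure* — that the
pipeline detects and localizes a known rigidification — not a quantitative
prediction for any particular antibody pair, which would require
long-timescale simulation of real structures as input.

## Numerical choices and degenerate inputs

* Internal atom/residue indices are 1-based (native R convention, matching
  the installed structural packages); author PDB residue numbers are
  preserved separately and never used for indexing.
* Kabsch superposition excludes reflections by sign-correcting the smallest
  singular vector; collinear inputs still return a proper rotation. The
  pairwise-RMSD fast path (singular-value form) switches to an explicit
  rotation when the result is near zero, where the fast form loses half its
  digits to cancellation.
* Mean-reference alignment iterates fit → mean until the mean moves < 1e-6 Å
  or 20 iterations; `pair_align()` then refits both ensembles' *original*
  coordinates to the converged reference in one shot, so comparing an
  ensemble with itself yields bitwise-identical frames and an exactly zero
  difference grid.
* Static ensembles: one cluster, zero RMSF/B, zero SD grid, zero plasticity.
  A single-frame ensemble warns and returns zero RMSF.
* Merge and representative ties break to the lowest index; cluster ids are
  ordered by decreasing size. k-means stages take an explicit seed and
  restore the caller's RNG state.
* DX grids store data z-fastest (the standard ordering) with grid positions
  at voxel centers; the corner origin and grid kind travel in comment lines
  at 17 significant digits so round-trips are metadata-exact.

## Known limitations

* Occupancy is full-volume, not a surface shell; a shell extraction (e.g.
  by erosion of the mean grid) is future work.
* No solvent-accessible-surface computation; the probe radius is a crude
  stand-in.
* The reversible MSM estimator is the symmetrization approximation, not the
  full MLE; error bars (Bayesian MSM) are out of scope.
* Binary trajectory formats (XTC/DCD) are not read; convert to multi-model
  PDB upstream.
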