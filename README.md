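# plastens

Surface plasticity and flexibility analysis of protein conformational
ensembles.

## What it is for

Affinity maturation tends to rigidify an antibody's antigen-binding loops,
most visibly the CDR-H3 loop: the matured ensemble populates fewer
conformations and presents a less variable molecular surface than its naive
(germline) precursor. `plastens` is for structural bioinformaticians who
have two conformational ensembles of a protein — e.g. trajectories of a
naive and a matured antibody fragment, as multi-model PDB files — and want
to quantify, compare and *localize* that rigidification.

The core method voxelizes each aligned ensemble into a per-frame binary
occupancy grid and summarizes it per voxel: with occupancy probability *p*,
the population SD is √(p(1−p)), maximal (0.5) where the protein is present
in half the frames — exactly the plastic regions where protein and solvent
alternate. After Gaussian smoothing (σ = 1.5 Å), the supra-threshold SD
volume integrates to a **global plasticity** score in Å³,

  P = Σ_{v : σ_v > θ} σ_v · h³,

and each contributing voxel is attributed to the residue of its nearest
heavy atom in the mean structure, giving a **per-residue plasticity
profile** that can be written into the B-factor column for colour-coding.
Around this core the package provides:

* average-linkage (UPGMA) clustering of frames by pairwise loop-Cα RMSD with
  a distance-cutoff termination — the cluster-count flexibility metric,
  with a cutoff sweep for robustness;
* 2D-RMSD matrices, RMSF and Debye–Waller B-factors (B = 8π²/3 · RMSF²);
* ψ-torsion sin/cos features and a linear collective-variable helper;
* a minimal kinetics stack: tICA, k-means microstates, Markov-state models
  (stationary distribution, implied timescales), PCCA-style macrostates and
  a Chapman–Kolmogorov test;
* multi-model PDB and OpenDX grid I/O, and a seeded synthetic-ensemble
  generator with closed-form ground truth for every metric.

## Worked example

```r
library(plastens)

pair <- naive_matured_pair(seed = 1)        # flexible vs. rigidified loop
report <- run_compare(pair$naive, pair$matured, config = run_config(),
                      output_dir = "out")
print(report)
```

```
Comparative rigidification report
  [a] clusters at 1.2 A: 71 | loop RMSF 2.600 A | global plasticity 1192.9 A^3
  [b] clusters at 1.2 A: 1 | loop RMSF 0.554 A | global plasticity 658.4 A^3
  difference: delta clusters +70, delta plasticity +534.5 A^3
```

Ensemble `a` (naive: loop σ 1.0 Å plus a two-state hop) fragments into 71
RMSD clusters at the 1.2 Å cutoff, fluctuates with 2.6 Å loop RMSF and
integrates to ~1193 Å³ of supra-threshold occupancy-SD volume; ensemble `b`
(matured: loop σ 0.2 Å) collapses to a single cluster with ~5× smaller
loop RMSF and ~45% less plasticity — the rigidification signature the
package is built to detect. `out/` then contains the DX grids (occupancy
mean/SD, smoothed SD, their difference), cluster-sweep and RMSF/plasticity
CSV tables, B-factor-coded PDBs of the localized profile, and `report.json`
with every number and parameter.

A command-line front end over the same functions ships in
`inst/cli/plastens.R` with subcommands `synth`, `cluster`, `flex`,
`plasticity`, `msm` and `compare`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "plastens.R", package = "plastens"))')" \
    compare -i naive.pdb --pair matured.pdb -o out/
```

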