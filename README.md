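# sitedock

Analysis toolkit for the downstream, statistics-and-geometry layer of a
membrane-transporter modelling study — the part that comes *after* the
expensive steps (homology modelling, molecular dynamics, docking engines)
have produced structures, trajectories and pose files.

It is aimed at structural bioinformaticians who have:

- docked ligand poses (AutoDock Vina PDBQT output) against one or more
  receptor conformations of an ABC transporter such as the ABCG2 multidrug
  exporter,
- lists of candidate binding-site residues,
- substrate / non-substrate category labels for the docked molecules, and
- Cα distance or RMSD time series from MD trajectories,

and who want reproducible, scriptable answers to questions like *which
binding site does each pose belong to*, *do substrates occupy a given site
more than non-substrates*, and *does a mutant change the mean or the
variability of an inter-helix distance*.

## What it computes

**Pose → site classification.** A receptor residue is in contact with a
pose iff any of its heavy atoms lies within a cutoff *d* (default 4.5 Å) of
any ligand heavy atom. With per-site contact counts
*c(s) = |contacts ∩ residues(s)|*, a pose is assigned to the unique argmax
site; a two-way tie between sites with a defined overlap region (Sites 1–2,
2–3, 1–3) yields that overlap label, anything else is unassigned. The four
built-in site definitions for the ABCG2 homodimer (39, 31, 22 and 24 unique
residues) match residues by `(resname, resid)` on both chains.

**Occupancy statistics.** Counts per (site, category) are normalized by
*n_molecules(category) × n_poses × n_conformations*, so cells are
comparable between categories of different size.

**Trajectory geometry.** Kabsch least-squares superposition and RMSD
series against a reference frame; per-frame Cα–Cα distances; block
averaging (consecutive windows of 10 frames by default, 5000 frames → 500
values); WT-vs-mutant comparison as `delta_mean` and `variance_ratio` of
pooled block-averaged replicates (descriptive only — MD frames are
autocorrelated, so no p-values are produced).

**Sequences.** Global affine-gap (Gotoh) alignment with BLOSUM62 and the
classic gap penalties (open 10, extend 0.5), percent identity/similarity
over gap-free columns, and CRAC cholesterol-motif scanning
(`(L/V)-X(1..5)-Y-X(1..5)-(R/K)`, one hit per central tyrosine).

**Synthetic data.** A deterministic generator (ideal helix bundles,
homodimer copies, pose clouds around declared sites, category-shifted
affinities, replicate distance series) so the full pipeline runs and is
testable entirely offline.

## Worked example

```r
library(sitedock)

co  <- synth_cohort(seed = 42)        # (25+14 molecules) x 20 poses x 6 conformations
res <- assign_cohort(co, cutoff = 4.5)
print(res$occupancy)
#> <OccupancyTable: 4680 poses over 14+25 molecules x 20 poses x 6 conformations>
#>            non-substrate substrate
#> S1                0.2857      0.20
#> S2                0.0714      0.72
#> S3                0.6429      0.08
#> S4                0.0000      0.00
#> ...
```

Substrates were generated to prefer Site 2; the normalized table recovers
that: 72% of all possible substrate poses land in S2 versus 7% of
non-substrate poses. Because counts are normalized per category, the
25-vs-14 cohort imbalance does not distort the comparison.

```r
wt  <- synth_distance_traj(data.frame(condition = "wt",  mean = 8,  sd = 1,
                                      n_frames = 500, n_replicates = 6), seed = 7)$wt
mut <- synth_distance_traj(data.frame(condition = "mut", mean = 10, sd = 2,
                                      n_frames = 500, n_replicates = 6), seed = 8)$mut
compare_dynamics(wt, mut, window = 10)
#> <DynamicsComparison (window 10)>
#>   wt : mean 8.01 A, sd 0.31 A (6 replicates)
#>   mut: mean 10.01 A, sd 0.59 A (6 replicates)
#>   delta_mean 2.00 A, variance ratio 3.49
```

The injected +2 Å shift and the doubled frame-level standard deviation are
recovered (after 10-frame block averaging a doubled frame SD appears as a
variance ratio near 4).

```r
scan_crac("MKVLAYAKDE")
#>   start end tyrosine_pos pattern_id
#> 1     4   8            6       CRAC
```

## Command line

Every stage is also a subcommand of the `exec/sitedock` script
(`simulate`, `assign-poses`, `site-stats`, `traj-distances`, `traj-rmsd`,
`align-stats`, `crac-scan`, `depth-annotate`); each run echoes its
configuration and writes a `manifest.json` with md5 checksums of every
output, and reruns on unchanged inputs are byte-identical:

```sh
sitedock simulate      --out-dir sim --seed 1
sitedock assign-poses  --receptor sim --poses sim/poses \
                       --sites sim/sites.tsv --categories sim/categories.tsv \
                       --cutoff 4.5 --out-dir run
sitedock site-stats    --assignments run/assignments.tsv --out-dir stats
```

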