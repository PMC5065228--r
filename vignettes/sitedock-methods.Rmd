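---
title: "sitedock: methods, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sitedock: methods, parameters, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

ABC transporters such as the ABCG2/BCRP multidrug exporter move chemically
diverse compounds across membranes, and a central question in their
structural analysis is *where* ligands bind along the translocation
pathway and *whether substrates and non-substrates are distinguished* at
particular pockets. A common workflow docks a cohort of known substrates
and non-substrates against several receptor conformations sampled from
equilibrated molecular-dynamics runs, then classifies each docked pose
into candidate binding sites by its residue contacts. A second, related
strand of analysis compares wild-type and mutant trajectories through
simple geometric read-outs: Cα–Cα distances between residues on different
transmembrane helices, and RMSD against the initial frame as a stability
check. `sitedock` implements this downstream layer — classification,
occupancy statistics, distance/RMSD series, sequence statistics — together
with a synthetic generator so the entire pipeline is exercisable without
any external data.

## Pose-to-site classification

A receptor residue is *in contact* with a pose iff any heavy atom of the
residue lies within `cutoff` of any heavy atom of the ligand, boundary
inclusive. Hydrogens are always excluded: pose files may or may not carry
polar hydrogens depending on how they were prepared, and excluding them
makes the contact definition independent of that choice.

Assignment uses only the per-site counts of contacted residues. The label
is the unique argmax site; a two-way tie between sites that have a defined
overlap region (Sites 1–2, 2–3, 1–3 — consecutive pockets on the proposed
translocation pathway) becomes that overlap label; any other tie, and
poses with no site contacts at all, are `unassigned`. Three-way ties are
deliberately not resolved by a priority order: the underlying site model
defines only pairwise overlap regions, and inventing a priority would
manufacture signal. Residue matching ignores chain identity because the
built-in site lists describe a symmetric homodimer whose sites exist on
both monomers; duplicated entries in those lists (the same position
contributed by both monomers) are collapsed on construction.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `cutoff` | 4.5 | Å | standard heavy-atom protein–ligand contact convention; the site model itself does not fix one, so it is exposed as `--cutoff` |
| occupancy denominator | molecules × poses × conformations | — | makes cells comparable between unequal category sizes |
| `window` | 10 | frames | matches the 10-frame block averaging used for all distance plots |
| `headgroup_width` | 8 | Å | typical phosphocholine headgroup extent above the hydrophobic core boundary |

The occupancy normalization is fixed to
`n_molecules(category) * n_poses_per_molecule * n_conformations`; the
source analyses state both normalizations without a formula, and this
product is the only choice under which a cell of 1.0 means "every pose of
every molecule in every conformation". Per-conformation tables can be
produced by passing `n_conformations = 1` on a subset.

## Trajectory statistics

`compare_dynamics` block-averages each replicate series, pools block
values per condition, and reports the mean shift and variance ratio. It
intentionally emits **no p-values**: MD frames are strongly
autocorrelated, replicates are few, and any standard test would be
anti-conservative. Effect sizes plus replicate counts are the honest
summary. Note one consequence of block averaging: a doubling of the
*frame-level* standard deviation appears as a variance ratio near 4 for
i.i.d. frames, and less for autocorrelated ones — the ratio is a
descriptive contrast, not an estimate of the frame-level variance ratio.

`rmsd_series` superposes each frame's selection onto the reference frame
with the Kabsch algorithm and uses the *same* selection for fitting and
measurement — the plain stability read-out, not a fit-on-core /
measure-on-loop split. The rotation is always proper (determinant +1),
guarding against reflections in degenerate SVD cases.

Membrane-depth annotation takes the slab (hydrophobic-core boundary planes
and headgroup width) as *input*, from an OPM-style orientation or a
config; computing a membrane orientation is out of scope, and residues are
labelled purely by their Cα z coordinate.

## Sequence statistics

The global aligner is an affine-gap Gotoh implementation with end-gap
penalties. A gap of length L costs `gap_open + gap_extend * (L - 1)`;
with the classic protein defaults (BLOSUM62, open 10, extend 0.5). Note
that conventions differ between tools: Biostrings charges
`open + extend * L`, so the two agree exactly when its opening penalty is
set to `open − extend` (the package's test suite uses that mapping to
cross-validate scores). Traceback ties are resolved deterministically —
diagonal, then up, then left — so aligned strings are reproducible across
platforms.

Percent identity uses gap-free columns as denominator; similarity
additionally counts pairs with a positive BLOSUM62 score. The denominator
choice is the main source of variation between published identity figures
(alternatives: all alignment columns, or the shorter sequence length), so
the acceptance machinery reports the all-columns variant alongside for
sensitivity.

The CRAC scan matches `(L/V)-X(1..5)-Y-X(1..5)-(R/K)` N→C, reporting one
hit per central tyrosine with the nearest flanks (shortest match).
Overlapping motifs are all reported. The mirrored CARC variant is not
scanned — the cholesterol-recognition analysis this supports concerns
classic CRAC motifs only.

## The synthetic world

The generator emulates the *shape* of the study's inputs, not their
physics:

- **Receptor**: six ideal α-helices (1.5 Å rise, 100° twist, 2.3 Å Cα
  radius) on a 10 Å circle, duplicated into a second chain to emulate the
  homodimer. Four sites are declared at anchor points between adjacent
  helix pairs at different membrane depths; a site's residues are all
  residues with Cα within 6 Å of its anchor (6–7 residues per site,
  mutually within 15 Å).
- **Conformations**: the default cohort perturbs the bundle with 0.25 Å
  per-coordinate Gaussian noise per conformation, keeping the six receptor
  conformations well under the ~1.3 Å maximum mutual RMSD reported for the
  equilibrated conformations the real docking used.
- **Poses**: rigid 6-atom octahedral dummy ligands (2.5 Å vertex radius)
  centered on the target site's Cα centroid plus isotropic Gaussian jitter
  (default 1 Å). No chemistry, no sterics — contact analysis only needs
  heavy-atom geometry.
- **Cohort**: 25 substrates and 14 non-substrates, 20 poses per ligand per
  conformation, 6 conformations — the published cohort shape. Substrates
  target sites S2/S1/S3 with probabilities 0.6/0.2/0.2, non-substrates
  0.1/0.45/0.45; these probabilities are the package's own encoding of the
  qualitative finding that Site 2 preferentially binds substrates while
  Sites 1 and 3 accept both. Affinities are N(−9, 1) kcal/mol for
  substrates and N(−7, 1) for non-substrates, matching the reported
  direction of the affinity-density contrast with a 2 kcal/mol shift.
- **Distance series**: i.i.d. Gaussian frames at stated mean/sd per
  condition, with an optional linear drift for divergence scenarios. The
  default recovery scenario (wild type 8 ± 1 Å, mutant 10 ± 2 Å, six
  replicates of 500 frames) encodes a "+2 Å and more variable" mutant.

Every stream derives deterministically from one integer seed; regenerated
outputs are byte-identical, and all written files carry the seed in a
header.

**What a green test does and does not establish.** The synthetic world has
no force field, no side chains, no solvent, no pose-scoring physics, and
its sites are geometrically compact and well separated. Green
classification-recovery and occupancy tests therefore establish that the
*bookkeeping* — contact detection, the assignment rule, the normalization
— is correct and that the pipeline can recover a planted signal of
realistic shape; they say nothing about whether a particular real
transporter's sites are correct, which depends on the upstream modelling
and docking this package does not perform.

## Numerical choices and degenerate inputs

- Contact boundary is inclusive (`d ≤ cutoff`), with a 1e-9 Å² tolerance
  absorbing floating-point noise at exactly the boundary.
- Kabsch requires ≥ 3 points; the reflection case is handled by flipping
  the smallest singular vector, so returned rotations are always proper.
- `block_average` averages a final partial block over its actual length;
  the canonical 5000-frame / window-10 case divides evenly so the choice
  is unobservable there, and averaging loses no data.
- Alternate locations in PDB input keep the highest-occupancy conformer
  (ties: first in file) — deterministic by construction.
- Blank element columns are inferred from the atom-name field by PDB
  convention (leading digit → hydrogen; known two-letter elements only
  when the name fills column 13).
- Pose ranks must be consecutive from 1; affinities out of order with rank
  *warn* rather than fail, since docking engines guarantee the ordering
  but hand-edited files may not.
- Side-chain truncation refuses proline (its ring shares backbone atoms)
  and refuses ALA targets when no Cβ exists.

## Known limitations

- Mapping Cα pairs between *non-identical* chains (needed to reproduce a
  cross-chain RMSD such as the 5DO7 chain A/B comparison) is out of scope;
  pairs must be pre-mapped from a sequence alignment before calling
  `kabsch_superpose`.
- The flat-key YAML config parser supports exactly the flat `key: value`
  subset it documents — no nesting, no lists.
- mmCIF and compressed trajectory formats are not read; multi-model PDB is
  the trajectory dialect.
- The offline environment cannot fetch the real ABCG2/ABCG5/ABCG8
  sequences or the 5DO7 structure; the three acceptance checks that need
  them run only when the user supplies the files described in
  `inst/extdata/real/README.md`, and fail otherwise by design rather than
  being silently skipped.
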