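---
title: "Methods: dimer trajectory analysis with dimertraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer trajectory analysis with dimertraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dimertraj` implements the standard in-silico workflow for judging
whether two G protein-coupled receptor (GPCR) monomers form a stable
dimer in a membrane simulation: geometric stability (RMSD/RMSF),
occupancy-filtered interface interaction analysis, Gromos conformational
clustering with medoid extraction, and a formation-energy balance between
the dimer simulation and the two monomer simulations. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic validation systems do and do not establish.

## Input model

Trajectories are multi-model PDB files: one `MODEL`/`ENDMDL` block per
frame on a regular time grid, typically three independent replicas per
system. This is deliberately the only trajectory dialect supported —
fixtures stay human-readable and the package stays free of binary-format
dependencies. Alternate locations other than `' '`/`'A'` are dropped with
a warning (the common deterministic convention); occupancy and B-factor
columns are ignored; coordinates are Ångström at the PDB's native
3-decimal precision, so `read_pdb(write_pdb(x))` is exact after one
quantisation.

Every atom carries an environment group — `protein:<chain>`, `membrane`,
`water` or `ion` — assigned from residue-name rules (POPC-style lipids,
the common water names, monatomic ions). Nonbonded parameters (partial
charge, Lennard-Jones σ and ε) come from a separate CSV keyed by
`(res_name, atom_name)`; unmatched atoms keep zeros with a warning. The
force field used to produce a real trajectory is typically proprietary,
so the package's energy model is an explicit, reproducible surrogate
(below) rather than an attempt to reconstruct force-field energies.

## Geometric stability

Superposition is the Kabsch algorithm with uniform weights: SVD of the
3×3 cross-covariance with the smallest singular direction sign-corrected,
so only proper rotations (det = +1) are returned and mirror images are
never "fitted". No mass weighting is applied anywhere — the inputs carry
no masses, and uniform-weight Cα fitting is the common convention for
receptor work. The residual RMSD is computed from the transformed
coordinates rather than the eigenvalue shortcut; the shortcut subtracts
two large, nearly equal coordinate sums and loses ~1e-7 Å to
cancellation, while the explicit residual is exact to machine precision
for congruent sets. Collinear or fewer-than-three point sets are
rejected.

- **RMSD series**: each frame fitted to a reference frame (frame 1 of
  each replica by default; configurable) on the analysis selection,
  Cα by default. The reference entry is exactly zero.
- **RMSF profile**: all window frames are fitted to the reference frame
  in a single pass (no iterative mean refitting — simpler and exactly
  testable), per-atom fluctuations are RMS deviations from the
  time-averaged position, and residue values average the residue's
  selected atoms. Under isotropic per-coordinate jitter σ the expected
  per-atom RMSF is σ√3; the superposition removes 6 rigid-body degrees of
  freedom out of 3N, so measured values sit a factor ≈ √(1 − 2/N) below
  that — about 1 % for N ≈ 100 fitted atoms, which is why the calibration
  tests use ≥ 100 atoms.

`build_dimer()` places two monomers on a two-chain template by Kabsch
fits of ≥ 3 mapped Cα atoms per chain, reporting per-chain fit RMSDs and
a count of inter-chain heavy-atom pairs closer than 2.0 Å (configurable).
The clash count is diagnostic only: relieving clashes by minimisation is
out of scope, so built dimers should be inspected before simulation.

## Interface interactions and occupancy

The interaction classes are hydrogen bonds, salt bridges, π-π and
cation-π, detected per frame from geometry alone (no bond topology
required). The criteria defaults follow common Maestro-style definitions
and are all configurable (`geometric_criteria()`):

| class | criterion | default |
|---|---|---|
| H-bond (with H) | d(H···A) | ≤ 2.8 Å |
| | donor angle D–H···A | ≥ 120° |
| | acceptor angle H···A–antecedent | ≥ 90° |
| H-bond (no H) | d(D···A), N/O heavy atoms | ≤ 3.5 Å |
| salt bridge | min distance between charged-site atoms | ≤ 4.0 Å |
| π-π face | centroid distance / interplanar angle | ≤ 4.4 Å, ≤ 30° |
| π-π edge | centroid distance / interplanar angle | ≤ 5.5 Å, ≥ 60° |
| cation-π | cation–centroid distance / axis angle | ≤ 6.0 Å, ≤ 45° |

Hydrogens are optional: when the topology contains any hydrogens the
strict three-condition test applies (H attached to its nearest same-residue
N/O within 1.3 Å, acceptor antecedent within 1.8 Å); otherwise the
heavy-atom fallback distance is used. Charged sites come from residue
templates (Arg NE/NH1/NH2, Lys NZ, Asp OD1/OD2, Glu OE1/OE2, OXT;
His optionally) or from nonzero formal-charge annotations, which is how
synthetic systems mark their sites. Rings come from Phe/Tyr/His/Trp
templates (both Trp rings); rings with missing atoms are skipped with a
warning. Keys are canonicalised so the two end orderings collide;
H-bond keys are at donor-atom/acceptor-atom resolution, salt bridges at
residue resolution with `basic`/`acidic` roles.

Occupancy of a key is the fraction of analysed frames in which it is
present, computed per replica and merged; the merged value is exactly the
analysed-frame-count weighted mean of the per-replica values. The first
20 ns of each replica are excluded as equilibration by default. The
protocol this package follows states an equilibration exclusion that
cannot be taken literally (it equals the full replica length), so the
default is anchored instead to the stability onset the same protocol
reports (~20 ns), and the exclusion is a per-run parameter. The retention
filter (20 % by default) applies to the *merged* occupancy — a cumulative
list over replicas — while the per-replica columns remain in the output
so either convention can be read off. The filter is monotone: lowering
the threshold never removes a retained key.

## Gromos clustering

Clustering runs on the merged, subsampled, equilibration-trimmed
trajectory with per-pair Kabsch fitting (not fit-to-reference), Cα
selection by default. The Gromos (Daura-type) iteration: among unassigned
frames, the one with the most unassigned neighbours within the RMSD
threshold (1.6 Å default) becomes a medoid; it and its neighbours form a
cluster and are removed. Ties go to the smallest frame index, and
clusters are ordered by size descending with ties broken by smaller
medoid index, so the procedure is fully deterministic. Limit behaviour is
exact: threshold above the matrix maximum gives one cluster, threshold
below the off-diagonal minimum gives all singletons. Whether clustering
should see pre-equilibration frames is genuinely open in the source
protocol; the pipeline trims them (consistent with the interaction
analysis) and the standalone functions accept any frame set. Cluster
ranks in `medoid_structure()` are 1-based, the R convention. The O(n²)
pairwise matrix is the only compiled code in the package (Rcpp/Armadillo),
as is usual for this step.

## Energetics and the formation energy

The pair potential is Coulomb `k q_i q_j / r` (k = 332.0636
kcal·Å·mol⁻¹·e⁻²) plus Lennard-Jones `4ε[(σ/r)¹² − (σ/r)⁶]` under
Lorentz–Berthelot combining rules, with a hard cutoff (9 Å default)
applied to **both** terms. The protocol being emulated states a cutoff
only for the coulombic part and computes energies with a proprietary
force field; this package's model is a deliberate, explicit surrogate —
energy *balances* are meaningful and exactly reproducible, absolute
kcal/mol values are not comparable to force-field numbers. There is no
periodic-boundary handling: synthetic systems are non-periodic, and
wrapped inputs are the caller's responsibility.

Per frame and protein chain the decomposition reports chain–chain (once
per unordered pair, emitted symmetrically), chain–membrane, chain–water,
chain–ion and internal energy. Internal energy is the intra-chain
nonbonded sum over atom pairs whose residues are ≥ 2 apart in sequence
(no bond topology is available, so same and adjacent residues stand in
for bonded exclusions; the separation is configurable). It is
nonbonded-only — whether a "chain rearrangement" energy should include
bonded terms is unknowable from the source protocol, and the surrogate is
labelled as such.

The dimer formation energy pairs replica r of the dimer with replica r of
each monomer system, averages each replica's terms over a trailing
window, and subtracts the monomer totals from the dimer total with the
chain–chain term counted once (a single monomer counted twice for
homodimers). The window default is the trailing 50 % of frames: the
source protocol's "last 250 ns" of 250 ns trajectories is ambiguous, so
the fraction is exposed as a parameter with a half-trajectory default
that matches its stated motivation (monomer energies are flat; dimer
interface energies need time to settle). The mean and SEM (sample
SD/√replicas) over replicas are reported, with negative values flagged
favourable.

## The synthetic generator: what it emulates, and what it does not

`generate_system()` builds a dimer system and the two monomer systems
that the formation-energy analysis needs: two idealized helical
mini-chains (10 residues × 4 sites: N, CA, C plus one side site) standing
side by side in a coarse lipid slab (~100 particles, two leaflets, carved
clear of the chains in every planted conformer placement), with ~200
waters and ~10 ions scattered above and below the slab, 500 frames × 3
replicas at 100 ps — a scaled-down replica of a production membrane
simulation that runs in seconds. Monomer systems reuse each chain with an
identical environment so environment terms cancel in expectation.

Ground truth is planted deterministically:

- **Occupancies** use a modular schedule — frame i (0-based, within
  replica) satisfies a planted interaction's geometry iff
  `i mod 10 < 10·occupancy` — with the end-point side sites placed
  exactly (exempt from jitter). Recovered occupancy therefore equals the
  target *exactly*, and remains exact under any equilibration exclusion
  or window that is a whole number of decades. This is why occupancies
  and conformer populations must be multiples of 0.1 and frame counts
  multiples of 10.
- **Conformers** are assigned by the decile of the frame index, with
  conformer 2 displacing chain B rigidly along the chain-separation axis.
  That axis is chosen because it changes the inter-centroid distance,
  which no global rigid fit can absorb — a displacement along the chain
  axis is largely absorbed by a compensating rotation and would leave the
  conformers barely separable. The 5 Å default gives fitted Cα RMSDs
  between conformers of roughly half the displacement, well above the
  1.6 Å clustering threshold, and jitter (σ = 0.1 Å default) keeps
  intra-conformer RMSDs far below it.
- **Energies** follow from the emitted parameter table (planted ±q
  interface charges on hydrogen-bond sites, ±1 on salt-bridge sites and
  ions, small backbone charges, LJ on everything); an independent
  pair-enumeration oracle (`reference_components()`) recomputes the
  components by a plain double loop for cross-checking at small sizes.

One seeded RNG drives all randomness; the same spec is bitwise
reproducible. What the toy systems do **not** emulate: real helix
packing, hydrogens (detection exercises the heavy-atom fallback; the
strict H-criteria are tested on constructed fixtures), realistic lipid or
water structure, periodic boundaries, and force-field energetics. Passing
tests therefore establish the correctness of the *analysis machinery* —
recovery of known geometry, occupancy arithmetic, clustering partitions,
energy bookkeeping — not the physical realism of any simulation.

## Pipeline, determinism and problem sizes

`run_analysis()` executes read → subsample → per-replica RMSD/RMSF →
merge → interaction detection → occupancy filter → BW annotation →
pairwise matrix → Gromos clustering → medoid export → energy components →
formation energy → LOWESS-smoothed H-bond count series, writing each
stage's tables as CSV/JSON plus the rank-1 medoid PDB. Missing optional
inputs (monomers, parameters, annotation) skip their stages with explicit
notices. Logs go to standard error; machine outputs contain no
timestamps, so identical config and inputs reproduce every output byte
for byte.

The subsampling stage implements the production convention of thinning a
100 ps recording grid to 500 ps before analysis. The packaged toy systems
are generated *at* analysis density (500 frames per replica), so their
run configurations use a stride equal to the recording interval and the
thinning arithmetic is exercised by dedicated tests at the production
sizes (2500 → 500 frames). Default analysis sizes throughout the tests —
500-frame replicas, 30-frame clustering instances, 50-atom energy
systems, 2000-frame RMSF calibrations — were chosen so the full suite
exercises every stage at meaningful scale while remaining quick on a
single CPU.

LOWESS smoothing of the count series is a faithful port of Cleveland's
algorithm (tricube-weighted local linear fits over the nearest
⌈frac·n⌉ points, bisquare robustness iterations, no interpolation
shortcut), with the neighbourhood fraction (default 2/3) and iteration
count (default 3) exposed. When the residuals are numerically exact —
e.g. perfectly linear data — the robustness scale collapses and further
iterations are skipped, matching the classic implementation.

Ballesteros–Weinstein labels are anchor-based: the user supplies, per
chain, each segment's residue range and its x.50 anchor (ICL2 is segment
34 by the common loop convention); labels are `seg.(50 + offset)`.
Anchors are never inferred from sequence motifs — motif inference is
error-prone and out of scope. The exact loop-numbering variant beyond the
offset rule is not standardised in the emulated protocol, so only the
offset rule is implemented.

## Known limitations

- Multi-model PDB is the only trajectory format; no DCD/XTC/TRR, no
  topology formats, no bond perception.
- The energy model is a surrogate: no bonded terms, no PME/periodicity,
  hard cutoff on both terms; absolute energies are not force-field
  comparable.
- Water-mediated bridges and intra-chain interaction networks are not
  analysed (the interface analysis is inter-chain).
- No automatic cluster-threshold selection or alternative clustering
  families; no energy minimisation of built dimers.
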