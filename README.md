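# dimertraj

Analysis of G protein-coupled receptor (GPCR) homo- and hetero-dimer
molecular-dynamics trajectories stored as multi-model PDB files.

Receptor dimerization — for example between chemokine receptors and other
class A GPCRs — is routinely probed in silico by running replicated MD
simulations of a dimer model embedded in a lipid bilayer and asking three
questions: is the complex geometrically stable, which inter-chain contacts
hold the interface together, and is dimer formation energetically
favourable relative to the separated monomers? `dimertraj` packages that
workflow for structural bioinformaticians, as composable R functions plus
one deterministic end-to-end pipeline:

- **Geometric stability** — Kabsch superposition (proper rotations only),
  per-frame RMSD series against a reference frame, and per-residue RMSF
  profiles, on a configurable atom selection (Cα by default).
- **Interface interactions** — per-frame geometric detection of
  inter-chain hydrogen bonds, salt bridges, π-π and cation-π contacts;
  occupancy per replica and merged over replicas, with an equilibration
  exclusion and a retention filter at 20 % merged occupancy by default.
  Occupancy of an interaction is the fraction of analysed frames in which
  its geometric criteria hold:

  `occ(k) = |{frames : criteria(k) satisfied}| / |analysed frames|`

- **Conformational clustering** — pairwise fitted-RMSD matrix (compiled
  kernel) and Gromos (Daura-type) clustering at a threshold (1.6 Å by
  default): repeatedly take the frame with the most neighbours within the
  threshold as a medoid, remove it and its neighbours, and continue. The
  medoid of any cluster can be exported as a PDB structure.
- **Energetics** — a transparent nonbonded model, Coulomb
  `332.0636 q_i q_j / r` plus Lennard-Jones
  `4 ε [(σ/r)¹² − (σ/r)⁶]` with Lorentz–Berthelot combining rules and a
  hard 9 Å cutoff, decomposed per frame into chain–chain, chain–membrane,
  chain–water, chain–ion and intra-chain (internal) terms, and the **dimer
  formation energy**

  `ΔE_form = [E_AB + Σ_c (E_c,env + E_c,int)]_dimer − Σ_c [E_c,env + E_c,int]_monomer(c)`

  with the chain–chain term counted once, a single monomer counted twice
  for homodimers, the trailing window of each replica averaged, and the
  mean ± SEM over replicas reported. Negative values indicate favourable
  dimerization.
- **Ballesteros–Weinstein numbering** — anchor-based labels (`3.50` at the
  TM3 anchor, ICL2 as segment 34) for interface reporting and per-segment
  contact summaries.
- **Synthetic systems with planted ground truth** — a seeded generator
  that builds toy dimer and monomer systems (two helical mini-chains in a
  lipid slab with waters and ions) with exactly known interaction
  occupancies, conformer populations and energy components, so every
  pipeline stage is testable without external data.

## Worked example

Generate a seeded toy system and run the full analysis:

```r
library(dimertraj)

sys <- generate_system(synthetic_spec(seed = 1))
dir <- file.path(tempdir(), "toy")
write_synthetic_system(sys, dir)

cfg <- run_config(
  dimer     = file.path(dir, sprintf("dimer_rep%d.pdb", 1:3)),
  monomer_a = file.path(dir, sprintf("monomer_A_rep%d.pdb", 1:3)),
  monomer_b = file.path(dir, sprintf("monomer_B_rep%d.pdb", 1:3)),
  params     = file.path(dir, "params.csv"),
  annotation = file.path(dir, "annotation.yaml"),
  stride_ps = 100, frame_interval_ps = 100, equilibration_ps = 20000)

report <- run_analysis(cfg)
print(report)
#> dimertraj analysis report
#>   stages:  read -> subsample -> rmsd_rmsf -> merge -> interactions -> annotate -> cluster -> energy
#>   interactions: 4 keys, 3 retained at threshold
#>   clusters: 2 (top size 540 of 900 frames)
#> dimer formation energy: -134.187 +/- 1.982 kcal/mol (SEM, 3 replicas, trailing 50% window) [favorable]
```

The retained-interaction table recovers the planted occupancies exactly
and carries Ballesteros–Weinstein labels:

```r
report$occupancy[, c("kind", "res_a", "res_b", "occ_merged", "retained", "bw_a")]
#>          kind res_a res_b occ_merged retained  bw_a
#> 1       hbond     3     3        1.0     TRUE  3.50
#> 2 salt_bridge     9     9        0.5     TRUE 34.52
#> 3       hbond     5     5        0.3     TRUE  3.52
#> 4       hbond     7     7        0.1    FALSE 34.50
```

Reading the numbers: the generator planted four inter-chain interactions
at occupancies 1.0, 0.5, 0.3 and 0.1; the 20 % filter retains exactly the
first three. The two planted conformers (60/40 populations, chain B
displaced between them) come back as two Gromos clusters of 540 and 360
of the 900 post-equilibration frames. The formation energy is negative
(favourable) because the planted interface charges and contact geometry
attract; its per-replica values agree within a ~2 kcal/mol SEM:

```r
report$formation_energy$per_replica
#>         1         2         3
#> -135.5391 -136.7371 -130.2845
```

All tables are also written as CSV/JSON (plus the top-cluster medoid PDB)
when `out_dir` is set in the config; `run_analysis()` is deterministic —
identical config and inputs reproduce every output byte for byte.

A thin command-line wrapper is installed at
`inst/scripts/dimertraj.R` (`simulate` and `analyze` subcommands).

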