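# nanopep

Design and co-assembly analysis of minimalistic four-residue peptide drug
nanocarriers.

## The problem

Short peptides of the form **Ac-X₁X₂X₃H-CONH₂ / -COO⁻** co-assemble with
small-molecule cancer drugs (epirubicin, doxorubicin, methotrexate,
mitomycin-C, 5-fluorouracil, camptothecin, cyclophosphamide) and
Zn²⁺/NO₃⁻ ions into drug-carrying nanostructures. The histidine fixed at
position 4 coordinates Zn²⁺; the first three positions are designable.
`nanopep` implements the computational workflow around this system for
structural-bioinformatics users: composition design, sequence
optimization, assembly construction, and post-hoc structural analysis.

The core pieces are:

* **Charge-neutral composition solving.** Each modeled system of
  *p* peptides (charge *q*<sub>pep</sub>) and *d* drugs (charge
  *q*<sub>drug</sub>) is completed with the smallest ion counts
  satisfying `p·q_pep + d·q_drug + 2·n_Zn − n_NO₃ = 0` with
  `n_Zn ≥ min_zn` (Zn²⁺ is retained for His coordination). This
  reproduces the designed peptide:drug:Zn²⁺ ratios — 4:2:1 for
  EPI/DOX/MIT/5FU/CPT/CP and 4:2:2 for MTX.
* **An empirical association free-energy scorer** in the published
  Vinardo form — attractive gaussian and quadratic overlap repulsion on
  the atom surface distance, linear-switch hydrophobic and
  hydrogen-bond terms, 8 Å cutoff — plus a separable gaussian Zn²⁺
  coordination well (ideal 2.1 Å). The design objective is the mean
  association energy of drug copies with the rest of the system.
* **The "lock & design as you go" optimizer.** Each iteration mutates
  one of positions 1–3 of the locked sequence, drawing the replacement
  from BLOSUM62-derived substitution probabilities
  `P(b|a) ∝ exp(s(a,b)/T)`, evaluates the threaded design over
  scaffolds and drug poses, and re-locks only on strict improvement.
  Designs reached for every drug are *consensus peptides*, ranked by
  the consensus energy penalty
  `penalty(p) = mean_d [E(p,d) − min_q E(q,d)]`, with an
  aggregation-propensity track for secondary selection.
* **Assembly analysis.** Multicomponent cluster detection (connected
  components under a minimum heavy-atom distance cutoff, grid
  accelerated), encapsulation and composition statistics versus cluster
  size, geometric β-sheet assignment, drug mediation probabilities,
  Shrake–Rupley SASA / burial fractions, and energy-versus-burial
  profiles.

## Worked example

```r
library(nanopep)

pep <- peptide("FFWH", termini_spec("carboxylate"))
pep
#> <peptide> Ac-FFWH-COO-  net charge -1e

# designed composition for the EPI system: 4:2:1
solve_neutrality(4, pep, 2, drug_spec("EPI"))
#> $n_zn
#> [1] 1
#> $n_no3
#> [1] 0

# idealized ordered assembly: one drug pocket between two antiparallel
# peptide pairs, Zn2+ on the His imidazoles, NO3- for neutrality
ips <- build_ips(pep, drug_spec("EPI"))
ips
#> <snapshot> 8 molecules (4 peptide, 1 drug, 2 Zn2+, 1 NO3-), 114 atoms

mean_drug_association_energy(ips)
#> [1] -2.684  # kcal/mol: the EPI copy is favourably bound in its pocket

assign_beta_sheet(ips)
#> <beta_assignment> 4 peptides, 100% in beta-sheet-like configurations

zn_coordination_census(ips)
#> <zn_census> 2 Zn2+; His-coordinated: 100% (cutoff 2.5 A)
```

A short design run and cross-drug consensus:

```r
start <- peptide("LVFH", termini_spec("carboxylate"))
run <- lock_and_design(drug_spec("EPI"), start,
                       scaffolds = list(build_ips(start, drug_spec("EPI"))),
                       budget = 150, seed = 1, poses = drug_pose_set(4))
run
#> <design_run> drug EPI, seed 1: 150 iterations, 3 improvements
#>   locked: Ac-MMYH-COO- at -4.03959 kcal/mol
```

The locked energy trace is non-increasing by construction
(`plot(run)` shows proposals versus the locked envelope). Collect runs
per drug into `find_consensus()` / `consensus_table()` /
`consensus_energy_penalty()` to rank sequences that work for every
drug; a penalty of 0 means best-for-all.

Fixture snapshots emulating early-stage co-assembly at the designed
ratios come from `generate_random_snapshot()` and `plant_clusters()`
(the latter with exact ground-truth partitions), and are analyzed with
`detect_clusters()`, `encapsulation_profile()`, `composition_ratio()`,
`mediation_stats()` and `energy_burial_profile()`.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/nanopep.R fixtures --seed 7 --drug EPI --out out/
Rscript inst/cli/nanopep.R analyze --in out/fixture_EPI_seed7.pdb --cutoff 4.5 --out out/an
Rscript inst/cli/nanopep.R design --drug MTX --seed 2 --budget 200 --out out/design
```

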