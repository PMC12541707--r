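---
title: "Methods: peptide nanocarrier design and co-assembly analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide nanocarrier design and co-assembly analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopep)
```

`nanopep` models the co-assembly of minimal four-residue peptides with
small-molecule drugs and Zn²⁺/NO₃⁻ ions, and the evolution-guided design
of those peptides. This vignette records the models, parameter choices,
and numerical decisions behind the package, and what its synthetic
fixtures do and do not establish about real systems.

## The molecular representation

Peptides are reduced to backbone N, Cα, C, O atoms plus a single typed
side-chain pseudo-atom per residue. The pseudo-atom carries the
interaction identity of the side chain (hydrophobic, donor/acceptor,
aromatic, formal charge) and an element-based van der Waals radius;
this is the minimum resolution at which the pairwise scorer's typing
flags are meaningful. Full-atom side chains, protonation-state
prediction, and tautomers are out of scope. Histidine is fixed at
position 4, its pseudo-atom representing the deprotonated imidazole
nitrogen (`NE2`) that coordinates Zn²⁺. The N-terminus is always
acetylated (neutral); the C-terminus is amidated (0) or carboxylate
(−1), the latter adding an explicit anionic `OXT` atom.

Drug molecules ship as *synthetic toy geometries*: planar ring systems
and typed substituent atoms with realistic sizes, but not real
conformers. Their load-bearing properties are the net formal charge,
the atom typing, and the overall molecular size. The formal charges
(EPI/DOX +1, MTX −2, MIT/5FU/CPT/CP 0) are an assumption — the unique
assignment consistent with the designed component ratios and termini
chemistry — and are documented as such on the drug table.

Side-chain charges are the canonical pH-7 values (D/E −1, K/R +1, H 0)
and are static; the package does not model pH-dependent protonation.

## Charge-neutral compositions

Every modeled system is built neutral:
`n_pep·q_pep + n_drug·q_drug + 2·n_Zn − n_NO₃ = 0`. `solve_neutrality()`
returns the smallest `n_Zn ≥ min_zn` (each extra Zn²⁺ can always be
offset by two NO₃⁻, so the minimum is `max(min_zn, ceiling(−q_rest/2))`)
and the nitrate count follows by arithmetic. `min_zn` defaults to 1
because the designed systems always retain Zn²⁺ for His coordination
and fluorescence; with that constraint the solver yields the designed
4:2:1 ratio for the +1 and neutral drugs and 4:2:2 for the −2 drug.

## The empirical scorer

The pairwise potential follows the published Vinardo parameterization
on the surface distance `d = ‖r_ij‖ − R_i − R_j`:

| term | form | weight | range |
|---|---|---|---|
| steric gauss | `w·exp(−(d/0.8)²)` | −0.045 | always |
| repulsion | `w·d²` for `d < 0` | 0.8 | overlap |
| hydrophobic | linear switch 1→0 | −0.035 | `d ∈ [0, 2.5]` Å |
| hydrogen bond | linear switch 1→0 | −0.6 | `d ∈ [−0.6, 0]` Å |
| Zn coordination | `w·exp(−(r−2.1)²/(2·0.4²))` | −2.0 | center distance |

with a hard 8 Å cutoff on the center distance. The Zn term is a
separable, non-directional distance well between the metal and eligible
partners (His `NE2`, anionic oxygens) — a deliberate simplification of
directional metal-docking terms; its weight (−2 kcal/mol) makes a
coordinated Zn²⁺ comparable to a few hydrogen bonds. All weights and
shape parameters live in `scoring_params()` and round-trip through the
YAML config. Energies are reported in kcal/mol on the scale the weights
imply. Evaluation is continuous (no receptor grids). The association
energy of a molecule is the sum over all intermolecular atom pairs;
summing it over all molecules double-counts each unordered pair, an
identity the test suite checks to 10⁻⁹ relative error.

Atom radii follow the XS typing used by empirical docking scorers
(C 1.9, N 1.8, O 1.7, S 2.0, P 2.1 Å …); Zn²⁺ uses its bare-cation
ionic radius (0.74 Å).

## SASA and burial

`sasa()` is a Shrake–Rupley quadrature with a *deterministic*
golden-spiral point set (default 960 points/atom, probe 1.4 Å), so
results are exactly reproducible and exact for an isolated sphere.
Because the point set is fixed in the laboratory frame, translations
leave SASA exactly invariant while rotations re-sample the occlusion
pattern: agreement is then only to quadrature resolution (tested at 2%
with 960 points). The burial fraction is SASA in the full system over
SASA in isolation; a zero isolated SASA (impossible for positive radii)
is rejected as degenerate geometry.

## Ordered assemblies (IPS) and their perturbed variants

The idealized builder stacks *pocket units*: one drug centered between
two layers of antiparallel peptide pairs. The strand template uses a
3.5 Å per-residue rise with amide N and carbonyl O offset ±0.9 Å along
the hydrogen-bond axis, so an antiparallel partner at the standard
4.8 Å inter-strand spacing forms 3.0 Å N···O contacts; side chains
alternate ±z, placing residues 2 and 4 of the front pair and 1 and 3 of
the back pair against the drug. Layer separation defaults to 10 Å.
These values are configurable; they were chosen once to satisfy the
package's own β-sheet criteria and steric limits, not fitted to any
outcome. Zn²⁺ sits 2.1 Å beyond the His side chain along its direction;
NO₃⁻ ions are placed peripherally. The builder is purely deterministic.

The SES-like builder emulates compact, partially disordered assemblies:
centroid distances are scaled toward the system center by a requested
compaction factor — *clamped by bisection to the tightest sterically
feasible value* under the 0.7 × radius-sum overlap limit, since an
ideal assembly already near contact cannot compact arbitrarily — then
each molecule receives a seeded random rigid-body jitter (translation
bounded by the perturbation magnitude, rotation angle scaled with it),
re-drawn on clash and falling back to the unjittered position after
bounded retries. At perturbation 0 and compaction 1 the output equals
the input.

Rather than hard-coding a fixed set of scaffold variants, variant
construction (termini, unit count, spacing, perturbation, compaction)
is exposed through parameters.

## The design loop

`lock_and_design()` is a strict-improvement stochastic hill climb:

1. draw a position uniformly from {1, 2, 3} (His-4 immutable) and a
   replacement residue from the substitution model row of the current
   residue, self-substitution excluded and renormalized;
2. thread the candidate onto every scaffold (side-chain identity swap;
   geometry unchanged at this resolution) and score the mean drug
   association energy over every (scaffold, pose) pair, keeping the
   minimum;
3. re-lock only on strict improvement (ties reject, matching the
   lock/unlock semantics), and stop at the iteration budget or after a
   stall of consecutive rejections (default 200, configurable).

Substitution probabilities derive from the packaged BLOSUM62 score
table via `P(b|a) ∝ exp(s(a,b)/T)`; the table is a data file so any
20×20 log-odds matrix can be dropped in, and the temperature `T`
(default 1) flattens or sharpens the distribution. Revisited sequences
are re-evaluated and the best energy per sequence is kept. All
randomness flows from one seed; identical inputs give bitwise-identical
histories.

Consensus across drugs is the intersection of per-drug design records
(accepted-only by default, all-visited optionally). The consensus
energy penalty is the mean over drugs of the gap to the per-drug best,
`penalty(p) = (1/D)·Σ_d [E(p,d) − min_q E(q,d)]` — this concrete form
is the package's own choice of consensus metric; it has a zero floor
attained exactly by best-for-all peptides and is invariant to per-drug
additive shifts. Ranking ties break lexicographically. The
aggregation-propensity track defaults to the Chou–Fasman β-sheet
propensity sum over all four positions (Kyte–Doolittle hydrophobicity
and an aromaticity indicator are also packaged); the choice of scale is
a parameter because no single published aggregation metric is implied
by the design problem.

The planted-optimum property test drives the loop with a synthetic
separable objective (per-position bonuses F −1, Y −2, W −3, unique
optimum WWWH): a graded landscape that is reachable under
substitution-matrix proposals, unlike a single-step bonus, while
keeping the optimum unique. That test runs the full iteration budget
(stall disabled) because it measures what the budget can find, not the
early-stopping heuristic.

## Cluster analysis

Two molecules are connected when their minimum heavy-atom distance is
≤ the contact cutoff (default 4.5 Å, always reported in outputs);
clusters are connected components. Detection bins atoms into a cell
grid with edge equal to the cutoff and examines only adjacent cells —
exactly equivalent to the naive definition, which the test suite
verifies against an independent BFS oracle on 50 random snapshots.
Encapsulation profiles report per-bin and cumulative percentages per
component kind over the exact sizes present (singletons are size-1
clusters, so the cumulative percent at threshold 1 is 100 by
definition). Composition ratios normalize counts to a peptide base of
4; with zero peptides the raw counts are returned. Mediation follows a
contact definition: a drug mediates two peptides if it touches two
distinct peptides within the cutoff, and the three-body variant
additionally requires a Zn²⁺ contact. The representative cluster is
the largest in the final frame, ties broken by the lowest mean
per-molecule association energy. Time series are indexed by frame
order only; no physical time unit is implied.

## β-sheet assignment

Standard secondary-structure assigners are ill-defined for four-residue
peptides, so the package uses a purpose-built geometric criterion: a
peptide is strand-flagged when it shares ≥ 2 inter-peptide backbone
N···O contacts ≤ 3.5 Å with one neighbor whose strand axis (first to
last Cα) is within 30° of parallel or antiparallel. The reduced
representation carries no amide hydrogens, so the N–H···O angle test
(≥ 140°) applies only when hydrogens are present. All thresholds are
configurable through `beta_criteria()`. The assignment is exactly
invariant under rigid-body motion (it uses only internal distances and
angles).

## Synthetic fixtures: what they do and do not show

`generate_random_snapshot()` reproduces the *conditions* of early-stage
co-assembly starting states: the designed neutral component ratios,
random placement and orientation, and a minimum-separation constraint
(default 3 Å) in a box sized from a 5×10⁻⁴ Å⁻³ number density chosen so
fixtures contain both contacts and singletons at the default cutoff.
`plant_clusters()` builds chains of molecules with known partitions
(consecutive contact ≈ 3 Å, inter-cluster gaps ≥ 20 Å), giving exact
ground truth whenever `contact < cutoff < spacing`. These fixtures
validate the *operators* — detection, statistics, scoring identities —
not the physics: they contain no solvent, no dynamics, and no
thermodynamic sampling, so passing tests says nothing about real
encapsulation efficiencies or assembly kinetics, which require
molecular dynamics outside this package's scope.

Problem sizes in the test and acceptance suites were chosen as the
smallest that exercise every code path non-trivially: random fixtures
of 7–21 molecules (~150–450 atoms) for oracle comparisons, 50 seeded
design runs with budget 500 for recovery statistics, and 960-point
SASA quadrature against closed forms and a 10⁶-point Monte-Carlo
oracle.

## Numerical choices and degenerate inputs

* Strict `<` acceptance in the design loop; ties reject.
* Lexicographic tie-breaks in penalty ranking and top-design selection.
* The neutrality solver errors only when forced counts would be
  negative; a snapshot with no Zn yields a census percent of `NA`
  rather than 0, and drug-free snapshots make the mean drug energy an
  error, not 0.
* Cluster detection of an empty or single-molecule snapshot returns
  singletons only; `composition_ratio()` rejects empty clusters.
* PDB output keeps 10⁻³ Å precision; round-trips restore full typing
  from the manifest plus molecule templates, so equality holds to
  format precision.
* The FNV-1a config hash is computed over canonical JSON in exact
  32-bit double arithmetic.

## Known limitations

* Toy drug geometries: binding-mode detail (π-stacking geometry,
  specific hydrogen-bond networks) is not represented; conclusions
  about a particular drug's pose are outside scope.
* The scorer is an empirical docking-style potential, not a force
  field; absolute energies are on the scorer's scale, and entropy,
  solvent, and polarization are absent.
* The Zn term is non-directional; coordination geometry (tetrahedral
  vs octahedral) is not enforced.
* Rotational SASA invariance holds only to quadrature resolution.
* No periodic boundary handling: inputs are assumed whole and
  unwrapped.
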