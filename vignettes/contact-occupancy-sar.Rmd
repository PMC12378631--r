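---
title: "Contact-occupancy fingerprints and PLS structure-activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-occupancy fingerprints and PLS structure-activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactsar)
```

## The problem

Congeneric inhibitor series often show potency differences that a static
crystal structure cannot explain: the binding site is plastic, and a ligand
can trade one electrostatic anchor for another. A typical example is a series
of macrocyclic peptidomimetic inhibitors of insulin-regulated aminopeptidase
(IRAP) whose C-terminal carboxylate can engage either of two active-site
arginines; which arginine dominates over a trajectory, not which appears in
the crystal pose, tracks with potency. `contactsar` implements the analysis
that makes that statement quantitative:

1. enumerate candidate ligand-residue contacts from MD trajectories,
2. keep only hydrogen-bond-capable pairs and aromatic ring pi-stacking,
3. collapse chemically equivalent distances to one representative per
   interaction,
4. convert each contact's distance series into a percent-of-trajectory
   occupancy,
5. regress pIC50 on the occupancy fingerprint by partial least squares (PLS)
   and rank contacts by their weights and coefficients.

The MD engine itself is out of scope: trajectories are *inputs*, read from
multi-model PDB. A synthetic-complex generator with programmable contact
dynamics and a known occupancy-to-potency model stands in for real
simulations, so every stage of the pipeline is testable end to end.

## Contact model

**Candidates.** A ligand heavy atom and a protein heavy atom form a candidate
pair if their distance is ever at or below `candidate_cutoff` (default 4.0 Å)
in a sampled frame. A distance exactly equal to a cutoff always counts as in
contact (a fixed `<=` convention used everywhere in the package). The
enumeration stride is configurable and defaults to every frame: sparse
snapshot-based enumeration is supported (`stride`), but on the short
trajectories this package targets, full-frame enumeration is strictly more
reproducible, and the stride actually used is recorded in the contact set's
provenance.

**Filtering.** Hydrogen-bond capability is element-based: both atoms must be
in `{N, O, S}`. No donor/acceptor or angle criteria are applied — the
candidates are *potential* hydrogen bonds measured on heavy atoms, and
occupancy cutoffs (below) do the discriminating. Pi-stacking candidates are
ring-centroid pairs: every annotated ligand ring against every aromatic
side-chain ring (PHE/TYR/TRP/HIS templates) whose centroids come within
`ring_candidate_cutoff` (default 6.0 Å, deliberately permissive) in at least
one sampled frame.

**Collapsing.** Chemically equivalent distances are merged so that one
interaction contributes one predictor:

* distances from the two carboxylate oxygens of a ligand carboxylate are
  replaced by one distance from the carboxyl carbon (`C_COOH`);
* distances to the NE/NH1/NH2 nitrogens of an arginine guanidinium are
  replaced by one distance to its CZ carbon;
* a pair hit by both rules (ligand carboxylate against an arginine
  guanidinium) collapses to a single `C_COOH`-CZ *salt-bridge* contact, never
  two half-collapsed ones.

An audit map from every original filtered pair to its collapsed contact is
retained on the contact set for reporting.

**Occupancy.** Occupancy is `100 * (#frames with distance <= cutoff) /
n_frames`, computed over *all* frames of each replicate regardless of the
enumeration stride. Cutoffs are per contact type and configurable; the
defaults are conventional geometric criteria:

| contact type | measured distance | default cutoff |
|---|---|---|
| hbond | heavy atom – heavy atom | 3.5 Å |
| collapsed carboxylate / guanidinium, salt bridge | representative – representative | 5.0 Å |
| pi-stack | ring centroid – ring centroid | 5.5 Å |

The representative-distance cutoffs are wider than the atom-atom one because
the representative carbon sits roughly one bond (~1.3 Å) behind the
interacting oxygens/nitrogens on each side. These defaults are declared
stand-ins, not literature constants; any serious application should set them
from its own force field and geometry conventions.

Replicates are aggregated by averaging their occupancies per ligand
(`replicate_policy = "mean"`), since one potency value exists per ligand; a
`"concat"` policy (one row per replicate, ligand label repeated) is kept for
sensitivity analysis, and the mean matrix equals the concat rows averaged by
ligand by construction. A contact never enumerated for some ligand fills as
0 % — absence from enumeration means the pair was never within the candidate
cutoff, which is an observation, not a missing value.

## The PLS model

The regression is single-response PLS (PLS1) fitted by NIPALS, implemented in
the package rather than delegated, because the model *is* the analysis and
its internals (weights, loadings, deflation) are reported objects. X columns
are centered and autoscaled to unit variance by default (`scale = FALSE`
available); zero-variance columns get scale 1 and contribute zero weight; y
is centered. For one response the NIPALS weight vector per component is the
normalized covariance `X'y` of the deflated blocks, so each component is
exact in one pass. Coefficients are reported on both the standardized and the
raw occupancy scale.

Correctness is pinned by three independent routes in the test suite: an
SIMPLS implementation written directly from its linear-algebra definition
(agreement to 1e-8 on random problems), `mixOmics::pls` predictions, and the
closed-form OLS equivalences (full-component PLS = least squares;
single-predictor PLS = the regression slope).

The default component count is `min(2, n_ligands - 1)`. With realistic
series sizes (4-12 ligands) more components mostly fit noise; the choice is
logged in the run report and configurable. With four or fewer ligands the
pipeline fits anyway but attaches an explicit small-n warning to the run —
refusing would make the canonical small-series workflow impossible, but the
coefficients of such a fit are indicative at best.

`contact_weights()` ranks one component's weights by absolute value, with an
optional filter to contacts of a named ligand group (for example only the
C-terminal carboxylate's contacts). Weight columns are unit-norm and score
vectors mutually orthogonal — both are tested invariants.

## The synthetic-complex generator

`synthetic_spec()` + `generate_sar_dataset()` emulate the study design the
pipeline targets: `n_ligands` (default 8) x `replicates_per_ligand` (default
3, the usual triplicate protocol) x `frames_per_replicate` (default 2000),
each replicate nominally 500 ns so the default protocol reports 1.5 µs of
sampling per ligand.

Each *contact program* plants one interaction: a template (salt bridge,
guanidinium hydrogen bond, plain hydrogen bond, pi-stack), a partner residue,
per-ligand target occupancies, and bound/unbound distances `d_on`/`d_off`.
Frame-to-frame dynamics are a two-state Markov chain with stationary bound
probability equal to the target occupancy and switching probabilities
`rate * occ` (off→on) and `rate * (1 - occ)` (on→off). The default
`switching_rate = 0.25` gives dwell times of a few frames — fast
hydrogen-bond-like dynamics at typical frame-saving intervals — so a
2000-frame replicate contains hundreds of switching events and its empirical
occupancy concentrates tightly around the target (the error shrinks as
1/sqrt(frames), a tested invariant). Markov switching was chosen over
Brownian dynamics precisely because the stationary occupancy is then exactly
controllable, which is what validation needs.

Geometry is schematic, not physical: each program occupies its own spatial
bay 50 Å from the next, the partner residue is fixed, and the ligand group
sits on the bay axis at the gap distance, so the governing distance equals
the gap exactly. Gap jitter is truncated Gaussian (sd 0.08 Å, clamped at 4
sd) and every atom gets small bounded positional jitter; spec validation
rejects any program whose `d_on`/`d_off` plus worst-case jitter could cross
its cutoff, so programmed states are always identifiable. What the generator
deliberately does *not* emulate: force-field energetics, solvent, correlated
multi-contact motions, binding-mode switches between contacts, and
metal-coordination chemistry. Passing tests therefore demonstrate that the
*pipeline arithmetic* is right, not that real MD occupancies behave this
cleanly.

The default per-ligand occupancy patterns are fixed design vectors: a linear
ramp (0.05–0.95) for the planted negative contact and golden-ratio
low-discrepancy sequences for the others, giving well-spread, modestly
correlated columns at any series size. The affinity model is
`pIC50 = 7.0 - 1.5 * occ(Arg929 salt bridge) + 1.5 * occ(Arg439 H-bond) +
0 * controls + N(0, 0.2)`; IC50s are back-computed in nM and the full ground
truth (coefficients, targets, true pIC50s, expected collapsed contact ids)
is written to a sidecar JSON. The planted signs mirror the motivating
finding: persistent Arg929 engagement tracks with *lower* potency, Arg439
with higher.

## Numerical and design choices

* **Indexing.** Atom indices are 1-based throughout, as in R; file residue
  numbers are preserved verbatim so crystal-structure labels ("ARG929")
  round-trip into contact ids.
* **Units.** Distances in Å, occupancies in percent, potencies as pIC50
  (−log10 of molar IC50), masses in Da.
* **Ties and edges.** `<=` at every cutoff; rolling windows truncate at the
  series edges; the fluctuation band of a smoothed series is ±1 rolling
  standard deviation (the plotted "fluctuations" of trend figures are not
  standardized in the field; the choice is recorded in output metadata).
* **Fold ratios** round half away from zero — the conventional reading of
  "n-fold higher" (14.16 → 14, 46.09 → 46, 2.5 → 3).
* **Monoisotopic masses** sum neutral-atom masses of the most abundant
  isotopes (¹²C = 12 exactly); the electron mass is ignored, matching how
  "[M+H]+ calcd" values are computed in organic-chemistry practice. The mass
  table is a curated CHNOPS-plus-halogens dictionary shipped with the
  package; determinism beats completeness here.
* **Which affinity enters Y** is whatever the ligand table provides (IC50 in
  nM, converted to pIC50); when a compound has both an IC50 and a literature
  Ki, the table's compiler decides, and the run log records the table used.
* **Trajectory dialect.** The tested interchange format is multi-model PDB;
  it is slow but dependency-free and byte-reproducible. Native binary
  formats can be adapted behind the same `trajectory` contract.
* **No periodic-boundary handling**: inputs are assumed binding-site-centered
  post-processed trajectories, which is how contact analyses are normally
  run.
* **Problem sizes.** The validation suite runs the full pipeline at 8 ligands
  x 3 replicates x 2000 frames (the generator defaults) for sign-recovery
  checks across 20 seeds, and single trajectories up to 1e5 frames for
  occupancy-convergence checks; these sizes make every property sharp while
  keeping a complete run interactive on one core.

## A worked run

```{r example, eval = FALSE}
library(contactsar)

# synthetic study: 8 ligands, 3 replicates each, planted Arg929/Arg439 pattern
ds <- generate_sar_dataset(synthetic_spec(seed = 1), dir = "demo")

# full pipeline from the written files
run <- run_all(file.path("demo", "config.yaml"), outdir = "demo_out")
run$contacts
head(run$coefficients[order(abs(run$coefficients$beta_standardized),
                            decreasing = TRUE), ])

# printed-arithmetic checks on a real ligand table
masscheck(read_ligand_table(system.file("extdata", "irap_ligands.csv",
                                        package = "contactsar")))
```

## Known limitations

* Hydrogen-bond detection has no geometry beyond distance; strong-but-bent
  and weak-but-linear interactions are not distinguished.
* Cation-pi, halogen bonds, hydrophobic contacts and water bridges are out of
  scope.
* The PLS stage offers no cross-validated component selection or permutation
  inference; with the small ligand counts this analysis targets, those would
  suggest a rigor the data cannot support.
* Occupancy treats frames as exchangeable: contact *lifetimes* and kinetics
  are invisible to the X matrix.
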