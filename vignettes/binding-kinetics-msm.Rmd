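---
title: "Estimating ligand binding kinetics with core-set Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ligand binding kinetics with core-set Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

## The model

This package estimates binding kinetics of a ligand to a membrane
receptor from unbiased simulation trajectories. The physical picture is a
ligand that starts free in solution (*bulk*), first touches the receptor
at an extracellular vestibule, and proceeds into the orthosteric pocket
either directly or through an additional intermediate pose; an
off-pathway pose exchanges only with the bound state. The analysis treats
the dynamics as a Markov jump process between conformational microstates
observed at a fixed lag time τ.

The stages, and the assumptions each one makes:

* **Contact featurization.** A frame is represented by which residues are
  within 5 Å of the ligand's "feature atoms" (oxygens, nitrogens, and
  carbons without bonded hydrogens — hydrogens and hydrogen-rich carbons
  carry little positional information), plus one flag marking whether any
  feature atom is within 10 Å of a Cα. The inequality is strict at the
  cutoff; a residue at exactly 5.000 Å is not a contact. Distances are
  computed without periodic wrapping: the flat-bottom restraint keeps the
  ligand near the receptor, so images never come closer than the primary
  copy. Both backbone and sidechain heavy atoms count toward residue
  contacts.

* **TICA.** The generalized eigenproblem `C_τ v = λ C₀ v` on the
  symmetrized lagged covariance yields the slowest linear coordinates of
  the feature process; eigenvalues are autocorrelations at the lag, so
  `|λ| ≤ 1` up to estimation error. Symmetrization makes the estimate
  invariant under time reversal, consistent with estimating a reversible
  model later. Rank deficiency (binary features are often collinear) is
  handled by projecting onto the eigenspace of `C₀` above `1e-8` times
  its largest eigenvalue before whitening. No kinetic-map scaling is
  applied to the projections.

* **Discretization.** Mini-batch k-means, seeded from data rows, with
  per-center learning rates `1/n`. The mini-batch variant is used because
  production data sets run to millions of frames; on small data it agrees
  with full k-means (checked in the tests).

* **Reversible MSM.** Sliding-window counts at lag τ; the largest
  strongly connected component of the count graph defines the active set;
  the detailed-balance maximum-likelihood transition matrix comes from
  the standard fixed-point iteration on symmetrized flows
  `x_ij = (c_ij + c_ji)/(c_i/x_i + c_j/x_j)`, converged to `1e-10`
  relative change. The spectrum is computed from the π-symmetrized
  similar matrix, so eigenvalues are exactly real.

* **Macrostates.** PCCA+ on the top right eigenvectors: simplex vertices
  by furthest-point seeding, fuzzy memberships by the vertex-inverse
  linear transform clipped to `[0, 1]` and renormalized. Four kinetic
  macrostates are then augmented by a fifth *bulk* state: any microstate
  whose frames are in the majority bulk-flagged (ties to bulk) moves to
  it. The split runs after the kinetic lumping, at cluster granularity,
  because bulk and vestibule interconvert quickly and would otherwise
  share a macrostate.

* **Core sets.** Microstates with macrostate membership ≥ 0.9 form cores;
  frames relabel to the last visited core (milestoning) and the model is
  re-estimated on core labels only. This removes transitions that exist
  only through brief excursions into border clusters — the dominant bias
  in passage times on noisy discretizations. A macrostate with an empty
  core falls back to its maximum-membership cluster with a warning.

* **Kinetics.** MFPTs solve `m_i = τ + Σ_j T_ij m_j` with `m = 0` on the
  target; the source value averages over bulk microstates with stationary
  weights. The association rate is `k_on = 1/(MFPT_on · C_eff)`, with
  `C_eff = 1/(N_A V)` the concentration of one ligand in the restraint
  volume (88 nm³ → 18.9 mM). Per-state free energies are
  `ΔG_s = −RT ln(π_s/π_bulk)`, reported raw and with an optional
  standard-state term `+RT ln(C_eff/1 M)`. A binding event runs from the
  last bulk visit to the first bound visit and is *indirect* iff it
  passes the intermediate macrostate. Errors come from resampling whole
  trajectories with replacement and re-estimating from the counts onward.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| contact cutoff | 5 | Å | heavy-atom contact convention |
| bulk cutoff | 10 | Å | separates solvent from interacting frames |
| TICA components | 5 | – | number of slow processes retained |
| TICA lag | 20 | frames | matched to the MSM lag candidate |
| microstates k | 800 | – | fine discretization for production data |
| MSM lag | 20 | frames | chosen from the implied-timescale plateau |
| macrostates | 4 (+ bulk) | – | bulk, vestibule, intermediate, bound, off-pathway |
| core threshold | 0.9 | membership | high-confidence cores |
| pathway min dwell | 2 | frames | ignores single-frame recrossings |
| temperature | 298 | K | equilibration temperature |
| box bounds | (−20,20,−20,20,−20,35) | Å | production flat-bottom restraint |
| bootstrap n | 100 | – | trajectory resamples |

The working lag is a data-dependent choice: `implied_timescales()`
tabulates `t_i = −τ/ln λ_i` across lags, and the analysis scripts use the
shortest lag on the plateau (5 frames = 0.5 µs for the synthetic study,
where the fastest true relaxation is ~0.6 µs).

## The synthetic ground truth

Raw trajectory sets of this size are typically not deposited, so the
package ships a generator whose defaults *are* the study conditions:

* a five-state chain (bulk, vestibule, intermediate, bound, off-pathway)
  at 0.1 µs per step whose rates were fixed, before any estimation, to
  reproduce the reported orders of magnitude: analytic bulk→bound MFPT of
  7.4 µs, ~30 % of binding events through the intermediate, fast
  bulk–vestibule exchange, and an off-pathway state reachable only from
  bound;
* an emission model mapping each state to a 4-residue contact block over
  20 binary features, each bit flipping independently with probability
  0.02 per frame (contact flicker in well-separated metastable poses is
  sparse), and a bulk flag that is 0 with probability 0.95 in bulk and
  1 with probability 0.98 elsewhere;
* a toy overdamped Langevin (Euler–Maruyama) ligand among Gaussian wells
  under the flat-bottom restraint, for exercising the geometric
  featurizers on continuous coordinates.

What the synthetic data deliberately does **not** emulate: temporally
correlated contact flicker, state-dependent noise, force-field or
sampling bias, and the sheer dimensionality of a real receptor (hundreds
of residues). Passing the recovery tests therefore demonstrates that the
estimators are correct and internally consistent — not that a given real
trajectory set is converged. The i.i.d. bit noise is in one respect
*harsher* than reality: it can teleport a single frame across feature
space, which real contacts cannot do. Two standard remedies absorb this:
core-set milestoning, and a minimum-dwell filter (2 frames) on the
pathway counter; with both in place the pipeline recovers passage times
within ~10 % and pathway fractions within ~1 percentage point at the
default study size (1000 trajectories × 1000 steps).

## Numerical choices and degenerate inputs

* Reversible-MLE convergence: `1e-10` max relative change, `1e5`
  iteration cap, error (not silent return) on non-convergence.
* `trim_ergodic` breaks size ties between strongly connected components
  by total count mass.
* PCCA memberships are clipped to `[0, 1]` and renormalized; crisp labels
  are argmax with first-index tie-break.
* Mini-batch k-means initializes from distinct data rows where possible;
  `k` greater than the frame count is an error.
* MFPT to an unreachable target raises an error; MFPT(source→source) is 0
  by convention. A source with zero stationary mass falls back to uniform
  weighting.
* Implied timescales for non-positive eigenvalues are `NA` (domain of the
  logarithm); failed lags in a scan are skipped with a warning.
* `λ = 0` TICA eigenvalues appear for white-noise features; components
  are normalized to unit `C₀`-norm so projections are scale-free.
* Zero-probability macrostates yield `+Inf` free energy with a warning.
* The flat-bottom restraint force is harmonic in the *boundary excess*
  (distance beyond the box), directed toward the reference receptor site
  — the gentler of the two readings of "proportional to its distance",
  and the one that leaves interior dynamics strictly unbiased.
* Dihedrals use the signed atan2 convention with results in
  `(−180°, 180°]`; rotamer outlier calls use circular distances on χ1.
* χ2 of phenylalanine is reported as the raw CD1 dihedral; no ring-symmetry
  folding into `(−90°, 90°]` is applied, since observed distributions
  (e.g. 106.8°) straddle the fold boundary.
* The assay temperature for `ΔG = RT ln K_i` defaults to 298 K;
  incubation was at 37 °C, but the reported free energy corresponds to
  room temperature within rounding, and the parameter is exposed.
* The adaptive-sampling respawn rule draws clusters with probability
  ∝ `1/(1 + count)` — a documented stand-in for count-based adaptive
  seeding; with all-zero counts it reduces to uniform.

## Design decisions that were genuinely open

* **"Carbons not attached to hydrogens"** is read as restricting carbons
  only; O and N are always feature atoms (the standard polar-atom
  convention).
* **Bulk-flag atoms**: the 10 Å flag uses the ligand *feature* atoms, not
  all ligand atoms, mirroring the contact-map selection.
* **PCCA variant**: PCCA+ with fuzzy memberships, because core sets need
  memberships; spectral-sign lumping would not provide them.
* **MFPT source weighting**: stationary-weighted average over bulk
  microstates (an equilibrium-start convention).
* **Error bars**: whole-trajectory bootstrap, `n = 100`; replicates
  without bulk→bound connectivity are skipped and counted, warning above
  20 %.
* **k_on convention**: the reciprocal formula `1/(MFPT_on · C_eff)`
  exactly; no replicate-level averaging of rates.
* **Kabsch pairing**: at least two paired atoms are accepted — RMSD is
  well defined for two points even though the rotation is then
  underdetermined.

## Problem sizes

The shipped analyses use 1000 trajectories × 1000 steps (10⁶ frames, 20
features, 50 microstates) for the recovery study, 10⁵-step Langevin runs
for the restraint checks, and 20 × 40-trajectory repetitions for the
bootstrap-coverage study; these sizes give per-quantity sampling errors
well below the tolerances they are checked against.

## Known limitations

* Linear TICA only; no kernel or deep variants.
* No Bayesian/hidden-Markov estimators and no transition-path-theory flux
  decomposition beyond direct pathway counting.
* No off-rate or affinity prediction from the MSM: populations inside the
  restraint volume underestimate the binding free energy severely when
  the bulk basin is artificially small, which is why the per-state ΔG
  values are reported relative to the restrained bulk and compared
  against the assay-derived ΔG only qualitatively.
* Structure superposition requires a user-supplied atom pairing; there is
  no automatic sequence alignment or Ballesteros–Weinstein numbering.
* The PDB reader handles ATOM/HETATM, altloc and element inference; it is
  not a general MD-format reader (no DCD/XTC).
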