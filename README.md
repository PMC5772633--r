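# bindkin

Markov state model (MSM) analysis of ligand binding kinetics and
thermodynamics, built for the study of a small-molecule antagonist binding
to the dopamine D3 receptor through its extracellular vestibule.

## What it does

Given molecular dynamics trajectories of a protein–ligand system, the
package estimates how fast and by which routes the ligand binds:

1. **Featurization** — each frame becomes a binary residue contact map
   (residue in contact iff any protein heavy atom is < 5 Å from a ligand
   feature atom: ligand O, N, and C without bonded H) plus a single bulk
   flag (any feature atom < 10 Å from a protein Cα).
2. **TICA** — the contact map is projected onto the five slowest linear
   collective coordinates, solving `C_τ v = λ C₀ v` on the symmetrized
   lagged covariance.
3. **Discretization** — mini-batch k-means (default 800 microstates).
4. **MSM** — sliding-window transition counts at a lag τ, trimmed to the
   largest ergodic component, and a maximum-likelihood reversible
   transition matrix `T` with detailed balance `π_i T_ij = π_j T_ji`;
   implied timescales `t_i = −τ/ln λ_i` guide the lag choice.
5. **Macrostates** — PCCA+ spectral lumping into 4 metastable states, a
   5th bulk state split out by the bulk flag, and core-set milestoning
   (membership ≥ 0.9) with model re-estimation to suppress spurious
   recrossings at cluster borders.
6. **Kinetics** — mean first passage times from the linear system
   `m_i = τ + Σ_j T_ij m_j`; the association rate
   `k_on = 1 / (MFPT_on · C_eff)` where `C_eff = 1/(N_A V)` is the
   effective concentration of one ligand in the flat-bottom restraint
   volume `V` (88 nm³ → 18.9 mM); per-state free energies
   `ΔG_s = −RT ln(π_s/π_bulk)`; direct vs indirect binding-pathway
   fractions; trajectory-bootstrap errors.

Companion modules handle radioligand assay arithmetic (logistic IC50
fits, the Cheng–Prusoff conversion `K_i = IC50/(1 + L/K_d)`, mutant fold
shifts `K_i^mut/K_i^wt`, `ΔG = RT ln K_i`) and structural geometry
(signed dihedrals, χ1/χ2 rotamers, Kabsch superposition and RMSD,
circular rotamer-outlier detection, representative-pose selection).

Because the raw simulation data of such studies are rarely deposited, a
synthetic-data module generates ground-truth discrete binding chains and
toy Langevin trajectories with known kinetics, so every stage of the
pipeline is verifiable end to end.

## Worked example

```r
library(bindkin)

chain  <- default_binding_chain()                       # 5-state truth
dtrajs <- sample_discrete_trajectories(chain, 1000, 1000, seed = 131)
emb    <- embed_chain_features(dtrajs, chain$n_states, seed = 132)

cfg <- pipeline_config(k = 50, tica_lag = 5, msm_lag = 5,
                       frame_interval = chain$lag_time, seed = 7)
res <- run_binding_pipeline(emb$contacts, emb$flags, cfg)
res$report
#> Kinetics report
#>   MFPT(on)   : 6.57 (bulk -> bound)
#>   C_eff      : 18.9 mM (V = 88 nm^3)
#>   k_on       : 8.07e+06 /M/s
#>   events     : 1767 (indirect fraction 0.29)

analytic_mfpt(chain, "bulk", "bound")$time   # 7.43 us (truth)
analytic_indirect_fraction(chain)            # 0.2996 (truth)
```

The recovered bulk→bound mean first passage time (6.57 µs) sits within
12 % of the analytic truth of the generating chain, the indirect-pathway
share (29 %) within one percentage point, and the five macrostates match
the true state labels on >99 % of frames.

The numbered scripts under `analysis/` run the full study: ground-truth
simulation, toy-trajectory featurization, the MSM/kinetics pipeline with
bootstrap errors, assay arithmetic, and rotamer geometry; each writes its
tables under `results/`.

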