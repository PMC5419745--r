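# idpevo

Tools for studying how protein–protein interactions involving
intrinsically disordered domains emerge and evolve, built around the
CID/NCBD system: the CREBBP-interacting domain (CID) of the NCOA
transcriptional coactivators and the nuclear coactivator binding domain
(NCBD) of CREBBP/p300, two disordered domains that bind each other by
coupled folding and binding. The package covers the full computational
arc of an "evolutionary biochemistry" study — reconstruct ancestral
sequences, count what changed along lineages, fit the thermodynamics of
resurrected variants, and analyze weighted structural ensembles — plus
a desk-scale implementation of the Bayesian ensemble-determination
machinery (metainference with parallel-bias well-tempered
metadynamics) on analytic toy systems.

## What it computes

- **Ancestral sequence reconstruction** (`marginal_ancestral`,
  `site_log_likelihood`): Felsenstein pruning on a fixed rooted tree
  under GTR-form amino-acid models (packaged JTT), with discrete-gamma
  rate classes (`Γ(α)`, k categories, probability-weighted mean rate 1)
  and an invariant-sites class. Marginal posteriors
  `P(state at node | data)` per site; gaps and masked residues (`X`)
  are missing data; indels are placed by a separate binary Fitch
  parsimony pass (`reconstruct_indels`). Alignment hygiene:
  `mask_low_confidence` (confidence < 0.5 → `X`) and
  `strip_gappy_columns` (keep gap fraction < 0.95). Sites with ML
  posterior < 0.7 are reported with ordered alternative residues
  (`ml_sequence_with_alternatives`).
- **Domain change rates** (`count_changes`, `cumulative_profile`):
  substitutions plus indel events (maximal one-sided gap runs),
  normalized per domain residue and accumulated against node ages in
  Myr.
- **ITC binding** (`predict_heats`, `fit_binding`): the single-site
  Wiseman isotherm with bound fraction
  `Θ = (1 + x + r − √((1+x+r)² − 4x))/2`, `x = X_t/(nM_t)`,
  `r = K_d/(nM_t)`, perfusion dilution tracking, and least-squares fits
  of `(n, K_d, ΔH, offset)` with c-value flags for weak binders;
  `summarize_kd` and `relative_affinity` aggregate constants.
- **Two-state denaturation** (`fit_single`, `fit_global_shared_m`,
  `delta_g`): CD at 222 nm versus urea (RT at 283.15 K) or TFE
  (dimensionless exponent), linear baselines,
  `f_D = 1/(1 + exp(m([D]₅₀ − x)/RT))`, global shared-m fits, and
  `ΔG_D-N = m·[D]₅₀` with quadrature errors.
- **Ensemble observables** (`contact_map`, `interface_summary`, `rmsf`,
  `helix_profile`, `radius_of_gyration`, `fes_2d`, `reweight`):
  weighted multi-model PDB ensembles; strict 0.5 nm heavy-atom
  contacts; >5% interface populations; iterative weighted-Kabsch RMSF;
  dihedral-window helix populations; free-energy surfaces
  `F = −kT ln ρ` over (helix fraction, R_g).
- **Metainference + PBMetaD toys** (`metainference_energy`,
  `sample_sigma`, `deposit_gaussian`, `run_sampler`, `final_weights`,
  `convergence_check`): the Gaussian metainference energy over N
  replicas with on-the-fly error sampling, well-tempered parallel-bias
  metadynamics (bias factor γ = 16, intervals with clamped borders),
  final-bias reweighting `w ∝ exp(+B/k_BT)` and second-half
  free-energy drift diagnostics.
- **Synthetic data** (`simulate_msa`, `simulate_itc`,
  `simulate_denaturation`, `simulate_ensemble`, `make_toy_system`):
  seeded generators producing exactly the formats the analyses read.

## Worked example

```r
library(idpevo)
library(ape)

# the ten measured Kd values between ancestral D/P NCBD variants and
# 1R CID variants, packaged as plain text
kd <- read.csv(idpevo_extdata("dp_1rcid_kd.csv"), comment.char = "#")
s  <- summarize_kd(kd$kd_uM)
sprintf("D/P NCBD - 1R CID: Kd = %.1f +/- %.1f uM", s$mean, s$sem)
#> "D/P NCBD - 1R CID: Kd = 5.1 +/- 1.6 uM"
relative_affinity(s$mean, 0.071)   # vs the tightest extant pair
#> 71.5  (~70-fold weaker than the extant reference interaction)

# ancestral reconstruction on a toy vertebrate tree
tree  <- read.tree(text =
  "(((human:0.08,zebrafish:0.12)FT:0.10,lamprey:0.22)V:0.08,amphioxus:0.35)root;")
model <- substitution_model("jtt", alpha = 0.8, k = 4)
sim   <- simulate_msa(tree, model, length = 60, seed = 42)
post  <- marginal_ancestral(sim$alignment, tree, model, "V")
rep_  <- ml_sequence_with_alternatives(post, threshold = 0.7)
mean(post$ml_prob); length(rep_$flagged)
#> 0.94   # mean ML posterior at the vertebrate ancestor
#> 4      # sites below 0.7, reported with ordered alternatives

# refit a synthetic titration generated at the ancestral-complex Kd
sched <- titration_schedule()            # 20 x 2 uL, 20/200 uM, 25 C
itc   <- simulate_itc(n = 1, Kd_uM = 3.0, dH_kcal = -8,
                      schedule = sched, noise_frac = 0.02, seed = 1)
fit_binding(itc$heats, sched)
#> binding_fit: n = 1.013, Kd = 3.66 uM, dH = -8.54 kcal/mol (chi2 0.036)
```

The fitted 3.66 µM from one noisy titration scatters around the
generating 3.0 µM; the median over 50 seeds lands at 3.07 µM (see the
acceptance report below).

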