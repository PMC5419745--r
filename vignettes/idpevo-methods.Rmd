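---
title: "Methods: models, fits and samplers in idpevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, fits and samplers in idpevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpevo)
```

idpevo reimplements, as one tested pipeline, the computational layers of
an "evolutionary biochemistry" study of two interacting intrinsically
disordered domains — the CID domain of the NCOA coactivators and the
NCBD domain of CREBBP/p300. The pipeline spans four methodologically
distinct layers: ancestral sequence reconstruction on a fixed phylogeny,
lineage substitution/indel accounting, thermodynamic model fitting (ITC
binding isotherms, chemical denaturation), and Bayesian
ensemble-determination machinery (metainference with parallel-bias
well-tempered metadynamics) exercised on analytic toy systems. This
vignette records the models, the tunable parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
establish.

## Ancestral sequence reconstruction

**Model.** Amino-acid substitution follows a GTR-form reversible model:
`Q[i,j] = S[i,j] * pi[j]` with symmetric exchangeabilities `S` and
equilibrium frequencies `pi`, normalized so branch lengths are expected
substitutions per site. The packaged default is JTT; any GTR-form model
can be supplied. Rate heterogeneity uses `k = 4` equal-probability
discrete-gamma categories with *category means* (not medians) computed
from incomplete-gamma integrals, so the probability-weighted mean rate
is exactly 1 for any shape `alpha`; an optional invariant-sites class
enters as an extra rate-0 category with the gamma rates rescaled by
`1/(1 - p_inv)`.

**Likelihood and posteriors.** Per-site likelihoods come from
Felsenstein's pruning algorithm with per-node column rescaling (log
scale factors accumulated per site), transition matrices from the
spectral decomposition of the symmetrized rate matrix, and `P(0)`
special-cased to the exact identity so zero-length branches behave like
hard constraints. Marginal (not joint) posteriors at an internal node
combine the upward conditional likelihoods with a downward pass
(`U_root = pi`; children receive the parent's message times the
sibling-lifted conditionals through the transposed transition matrix),
weighted over rate classes. Marginal reconstruction matches the
per-site probability tables such studies publish per resurrected node.

**Hygiene rules.** Two pre-processing operations mirror standard
alignment hygiene: `mask_low_confidence()` turns every residue of a
column with confidence strictly below the threshold (default 0.5) into
`X`, and `strip_gappy_columns()` retains columns whose gap fraction is
strictly below the cutoff (default 0.95), returning the column map.
Both `-` and `X` are missing data in the likelihood (all-ones
conditional vectors). Indel placement is deliberately separated from
the residue model: a binary presence/absence Fitch-parsimony pass per
column, with ties resolved toward "present". The source study names no
indel algorithm for its reconstruction tool; Fitch parsimony is our
stand-in, not a claim about that tool.

**Uncertain sites.** `ml_sequence_with_alternatives()` flags sites whose
maximum posterior falls strictly below the threshold (default 0.7, the
cutoff used experimentally to decide which alternative residues to
synthesize) and lists the remaining residues in decreasing posterior
order, ties broken alphabetically by one-letter code — deterministic
and documented.

**Shape fitting.** `optimize_shape()` is a bounded one-dimensional
golden-section search on `alpha` (tolerance 1e-4), optionally
alternating with a `p_inv` search. Branch lengths are taken from the
input tree and never re-optimized: trees are estimated upstream by
dedicated tools, and re-fitting them here would silently change the
question being asked.

## Domain change accounting

`count_changes()` counts substitutions as columns where both sequences
carry differing residues; columns containing `X` in either sequence are
excluded from both the counts and the domain length (masked positions
carry no signal). An indel event is a *maximal run* of columns gapped
in exactly one of the two sequences, counted once regardless of length
(one biological event per run); per-column counting is available since
the convention is not fixed by the source material.
`cumulative_profile()` normalizes `(substitutions + indel events)` by
the descendant's non-gap residue count in the domain window and
accumulates the fractions against user-supplied node ages (the package
does no dating; ages such as 600/450/390 Myr are metadata). Nodes with
tied ages — successive whole-genome duplications — can be separated by
an explicit, arbitrary plotting offset.

## ITC binding isotherms

The single-site Wiseman model: with cumulative injected volume `v` into
a cell of volume `V0`, concentrations follow the perfusion convention
`M_t = M0 (1 - v/2V0)/(1 + v/2V0)` and
`X_t = X0 (v/V0)/(1 + v/2V0)`; the bound fraction is the quadratic root
`Theta = (1 + x + r - sqrt((1 + x + r)^2 - 4x))/2` with
`x = X_t/(n M_t)`, `r = Kd/(n M_t)`; cumulative heat
`Q_i = n Theta_i M_t,i dH V0` and per-injection heat
`dq_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2 + offset`. Working
units are µL/µM/µcal with `dH` in kcal/mol, so dissociation constants
read directly in µM. Fitting is least squares over
`(n, log Kd, dH, offset)` — `log Kd` keeps the constant positive and
makes the standard error multiplicative — with three log-spaced `Kd`
starts and the best chi-squared winner; standard errors come from the
Gauss–Newton covariance. Fits with a Wiseman c-value
(`n * M0 / Kd`) outside `[0.1, 1e4]` are flagged low-confidence, the
numerical counterpart of "stoichiometry not well determined" for weak
binders; `n` can be fixed to 1 in that regime. The default simulation
schedule (20 × 2 µL into 200 µL; 20 µM cell, 200 µM syringe) gives
c ≈ 4–300 across the study's Kd range — a sensible iTC200 design; the
actual instrument schedules are not published.

## Two-state denaturation

The observed CD signal interpolates two linear baselines through the
end-state population
`f_D(x) = 1/(1 + exp(m (midpoint - x)/RT))`. For urea, `m` is in
kcal mol⁻¹ M⁻¹ and `RT` uses 283.15 K (the melts were recorded at 10 °C
in 1 M TMAO; TMAO is treated as buffer, not modeled); for TFE the
exponent is dimensionless (`m` per %, 25 °C) and — since TFE *induces*
helix — the "denatured" state label simply denotes the TFE-induced
helical state. No free energy is reported for TFE, matching the source
tables. `fit_single()` is a 6-parameter least-squares fit with
multi-start over midpoint quantiles and m scalings (broad transitions
with short baselines invite local optima); fits are flagged when the
midpoint leaves twice the scanned range or a baseline is supported by
fewer than 3 points. `fit_global_shared_m()` fits one m across curves
with independent midpoints/baselines — the pooling the original
analysis used because single-curve m values of this small domain are
poorly determined. `delta_g()` is the linear-extrapolation product
`m × midpoint` with quadrature error propagation.

A caution the tests quantify: with a free 6-parameter fit, 3%-of-range
noise and a 0–8 M scan, the intrinsic statistical error of a single
midpoint is ≈ 0.2 M (verified by refitting from the true parameters —
it is not an optimizer artifact). Replicate medians are unbiased to
≈ 0.01 M. This mirrors the published precision (±0.1–0.3 M) and the
stated reason for shared-m fitting.

## Ensemble observables

Ensembles are multi-model PDB structures with per-model weights;
coordinates are held in nm internally (Å converted on read/write).
Weights come from final-bias reweighting `w ∝ exp(+B/kT)` computed with
a max-shift. Contacts are strict: two residues touch in a model iff any
heavy-atom pair is strictly within 0.5 nm; populations are weighted
model fractions. Interface summaries count inter-domain residue *pairs*
above the 5% population threshold (primary mode) with a residue-count
alternate, since the source figure caption is ambiguous between the
two; per-residue interface counts are normalized by the per-complex
maximum — the normalization constant is unstated in the source, and
this choice is flagged as ours. RMSF iterates weighted Kabsch
superposition onto the weighted mean structure to convergence
(1e-6 nm). Helix assignment is a dihedral window (`phi` in (−100, −30),
`psi` in (−80, −5)) with a run-length ≥ 4 gate — a geometric stand-in
for the chemical-shift-based secondary structure the study used, which
is out of scope; consequently absolute helix populations from this
package are not comparable to the published chemical-shift-derived
fractions, and are not treated as acceptance quantities. Free-energy
surfaces are `-kT ln` of weighted 2-D histograms, min-shifted to zero,
with empty bins unreachable (`Inf`).

## Metainference and parallel-bias metadynamics (toy scale)

The Gaussian metainference energy is implemented exactly as printed in
the source:

`E = sum_r { E_ff + kT sum_i [ (f_i(X) - d_i)^2/(2 sigma_r,i^2) + 0.5 log(2 pi sigma_r,i) + 0.5 log sigma_r,i ] }`

with `f_i(X)` the forward model averaged over replicas. The two half-log
terms are algebraically `0.5 log 2pi + log sigma`; whether additional
error-prior terms from the original metainference formulation were
intended cannot be determined from the printed expression, so it is
taken literally. Errors are Metropolis-sampled per replica and datum on
the log scale with the Hastings factor `sigma'/sigma` (detailed balance
in sigma-space), bounded in `[0.01, 10]` by default.

The molecular machinery (force field, solvent, chemical-shift forward
models) is replaced by analytic toy systems — the algorithms are
preserved, the chemistry is not. Sampling is Metropolis Monte Carlo;
PBMetaD holds one 1-D well-tempered bias per collective variable, the
applied bias being `-kT ln sum_j exp(-V_j(s_j)/kT)` with deposition
heights decayed by `exp(-V_j/((gamma-1) kT))` (bias factor 16 by
default) and split by the parallel-bias weights. The bias is clamped
constant outside each CV's interval. Grids have 512 points with linear
interpolation: at grid spacing ~0.01 against Gaussian widths ≥ 0.05 the
interpolation error is negligible next to the 0.5 kJ/mol deposition
quantum, and linear lookup keeps the per-step cost trivial in pure R
(a deliberate simplification from spline interpolation).

**Convergence accounting.** Free energy is estimated from the bias as
`F = -gamma/(gamma-1) V`, each estimate aligned to zero mean over the
biased interval (free energies are defined up to a constant). The drift
statistic is the maximum absolute deviation of the 10 second-half
checkpoint estimates from their average across the interval — the
quantity the original convergence analysis plots, with a 3 kJ/mol
acceptance bound.

**Two regime caveats the tests encode.** (1) The pointwise
well-tempered identity `V ≈ -(1-1/gamma) F` holds only where the
deposition Gaussian is narrow against the curvature of `F`, and is
systematically distorted within a few Gaussian widths of the clamped
interval borders; the identity check therefore uses width 0.05 and
excludes a 3-width edge margin. (2) At *fixed* sigma the stationary
deviation of the restrained replica mean from the datum has no trend in
the replica number N — for a harmonic prior it is exactly
N-independent, because prior and restraint both scale with N. The
physically meaningful trend arises because sigma contains the standard
error of the replica mean, which shrinks as `1/sqrt(N)`; the
convergence-with-N test scales sigma accordingly.

## Synthetic data: what a green test establishes

All generators seed R's Mersenne–Twister explicitly (inversion
normals), so recipes are bit-reproducible. The sequence simulator draws
the root from `pi`, assigns each site a rate class, evolves residues
with exact transition matrices, and applies a deletion-only indel
process (Poisson events per branch, geometric lengths of mean 2) whose
gaps are inherited — sufficient for testing indel counting and
missing-data handling, but not an insertion model. The ITC and
denaturation generators add i.i.d. Gaussian noise to the exact forward
models; real baselines drift and real heats have correlated errors,
which recovery tests here do not probe. The ensemble generator builds
ideal-geometry backbones from dihedrals (NeRF internal-coordinate
placement), samples helicity cooperatively per constant-probability
window (all-or-none two-state folding of each segment, so realized
populations equal nominal probabilities under the run-length rule),
rigidly places the second chain to pin a chosen inter-chain contact,
and jitters atoms isotropically — there is no side-chain packing, no
excluded volume and no realistic disorder ensemble. Green recovery
tests therefore establish the *estimators* are correct and calibrated
on data satisfying their assumptions; they do not reproduce the
published trajectories, alignments or chemical-shift ensembles, which
would require the original data.

## Known limitations

- Marginal ASR only; joint reconstruction and branch-length
  re-estimation are out of scope.
- The indel reconstruction is parsimony, independent of branch lengths.
- The ITC dilution convention is one of several in instrument software;
  generator and fitter share it, so recovery tests cannot detect a
  convention mismatch against other implementations.
- Helix assignment is geometric, not chemical-shift-based.
- The PBMetaD sampler is Monte Carlo in low dimension; it makes no
  claim about molecular force fields or explicit solvent.
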