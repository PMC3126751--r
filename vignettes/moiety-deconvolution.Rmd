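---
title: "Moiety deconvolution of isotopologue distributions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moiety deconvolution of isotopologue distributions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moietyfit)
```

## The model

A modular metabolite is described by a *moiety state space*: an ordered
set of subunits, each with a carbon count and a set of allowed 13C label
counts (its isotopomer states). For UDP-GlcNAc labeled from
[U-13C]-glucose the default space is

```{r}
udp_glcnac_space()
```

The all-or-none restriction on glucose, ribose and acetyl encodes the
biochemistry: those units are incorporated intact (or come from
pre-existing unlabeled pools), whereas the uracil ring mixes carbon from
aspartate — itself scrambled through the Krebs cycle — so all of 0–3
ring labels are allowed. The fourth ring carbon comes from bicarbonate
and stays unlabeled under glucose tracers, which is why the default
uracil maximum is 3 and mass m17 is unreachable; this lives in the model
definition (`inst/extdata/udp_glcnac.json`), not in code, so other
tracers can declare other state sets.

Each subunit's state mole fractions sum to one (closure), leaving
`Σ (states − 1) = 6` free parameters. The forward map is a convolution:
the predicted mole fraction at mass shift *n* sums the products of
subunit fractions over all joint states with total label *n*. Masses
below the maximum with no supporting state are reported as exact zeros
rather than omitted, so signal observed there is visible as pure
residual. The implementation is checked against an independent
brute-force enumeration over all joint isotopomers (1e-12) in the test
suite, together with profile normalization, subunit-order invariance and
monotonicity of the mean mass shift in any labeled fraction.

Closure tolerance is 1e-9: parameter vectors within it are renormalized
(float round-trips through JSON/TSV should not error), larger violations
are rejected. When several states of a subunit are omitted from an input
parameter set they default to zero; a single omitted state is taken as
the closure complement.

## Natural-abundance correction

Every carbon that is not tracer-derived is 13C with probability
p ≈ 0.011, so a species with *e* enriched carbons spreads over masses
*e + j* with binomial weights `C(C−e, j) p^j (1−p)^(C−e−j)` (C = 17 for
UDP-GlcNAc). Stripping solves this triangular system from the lowest
mass upward — equivalent to sequential subtraction of each corrected
species' envelope from the higher masses, but exactly invertible:
re-convolving the stripped vector reproduces the input to numerical
precision, which the tests assert at 1e-9. Only 13C is corrected; at
FT-ICR-MS resolution the 2H/15N/18O isotopologues are resolved away.
Small negative results (noise at <1% precision) are clamped to zero with
a warning and the clamped mass reported; clamping can be disabled.
Correction order is strip first, then normalize to mole fractions — the
order is not dictated by the normalization definition, and is recorded
here as a package decision.

At t = 0 a pure-unlabeled C17 pool keeps `(1 − 0.011)^17 ≈ 0.83` of its
signal at m0, the standard sanity check for the correction settings.

## The GAIMS optimizer

The target function is the unweighted sum of squared residuals on mole
fractions, `T = Σ_n (I_obs,n − I_calc,n)²`. It is minimized by a hybrid
simulated-annealing/genetic search with the published hyperparameters:
population 20, 5% crossover rate, 3 free variables mutated per step, a
linear annealing regime, 10⁶ steps, 50 independent repeats.

Where the published description leaves the mechanics open, the package
makes these choices:

* **Steady-state replacement.** A mutated child competes only with its
  parent (selected by binary tournament) and replaces it only if
  strictly better. We first implemented the more obvious
  replace-the-worst-member scheme and found it homogenizes the
  population into a single basin long before the annealing schedule
  cools: with the 48 h UDP-GlcNAc profile, half of all 1e5-step runs
  terminated in a local minimum (T ≈ 1.4e-3) in which the acetyl and
  uracil two-label states are partially exchanged. Parent-wise
  replacement keeps the 20 members semi-independent, and the failure
  mode disappears (29/30 random seeds recover all parameters within
  1e-3 at 1e5 steps; ~1e-4 at the default 10⁶ steps).
* **Crossover protection.** A crossover child must beat *both* parents
  and replaces the worse one. Unconstrained recombination between a
  converged member and a still-exploring member otherwise steadily
  deletes unrefined basins — measurably worsening recovery.
* **Annealing.** The per-variable perturbation magnitude decays linearly
  from 0.5 to 1e-4 over the run; perturbations are uniform on
  [−scale, scale].
* **Closure by projection.** After mutation/crossover, free variables
  are clamped to [0, 1] and each subunit block is renormalized onto its
  simplex, so every candidate ever evaluated is feasible.
* **Determinism.** A self-contained 64-bit RNG (splitmix64) is seeded
  from the run seed; repeats derive their seeds from the master seed by
  a fixed affine map mod 2³¹−1. Identical seed, settings and data give
  bit-identical results, independent of R's RNG state.
* **Mode-consistent averaging.** `mean_params` averages the repeats
  whose final objective lies within `multimodal_tol` (1e-4) of the best
  repeat. An average across distinct local basins is not a parameter
  estimate — it lies between modes and fits the data worse than either —
  and, because model selection evaluates the objective at the averaged
  parameters, it systematically inflated the simpler model's criterion.
  `sd_params` is computed over *all* repeats, so residual multimodality
  (as reported experimentally for the acetyl unit) remains visible, and
  a `multimodal` flag is raised when repeat objectives disagree.
* **Reading of "three variables per step".** Applied per mutated
  candidate, capped at the number of free variables.

`steps` is configurable down to desk scale; tests use 2e4–1e5 steps and
state so, while the shipped default remains 10⁶.

## Model selection

Variant labeling models are generated from a grammar of per-subunit
alternative label sets and ranked by the least-squares information
criterion `AIC = n ln(RSS/n) + 2k`, with the small-sample correction
`AICc = AIC + 2k(k+1)/(n−k−1)` on by default since n = 17 per
timepoint. The criterion is evaluated at the (mode-consistent) mean of
the repeat optima — evaluating at averaged optimized values penalizes
models whose parameters are poorly determined — and summed across
timepoints, which are fitted independently. Two numerical guards:

* per-timepoint RSS is floored at 1e-12 before the log — the corrected
  t = 0 profile is a single peak that many variants fit to machine zero,
  and without the floor every variant scores −Inf and the ranking is
  void; at the floor the parameter penalty decides, as it should for
  indistinguishable fits;
* a variant whose fit or criterion fails (e.g. k + 1 ≥ n for AICc) is
  ranked last with its error message rather than aborting the
  selection.

The shipped grammar expands glucose ×2, ribose ×3, acetyl ×3 and uracil
×3 alternatives into 54 variant models, matching the published scale of
"over 40". Selection-consistency tests use an 8-variant subset and
reduced optimizer settings to stay within the test-time budget; with
them the generating model is selected in ≥ 90% of 20 replicate
simulations at 1% noise, and the full-acetyl variant ({0,1,2}) always
scores worse than the base model on base-model data. Boundary
extensions (adding a state whose true fraction is 0) are the hardest
competitors for any AIC-type criterion; the observed ~5% overselection
is inherent to the criterion, not to the optimizer.

## Kinetics

Deconvoluted component timecourses are fitted by nonlinear least
squares (`stats::nls`, Gauss–Newton) to a saturating rise
`b(1 − e^{−kt})` or a single-exponential decay `I(0)e^{−kt}`. Starting
values come from a log-linear regression of the suitably transformed
data and the curve endpoints, with a Nelder–Mead fallback on the SSE if
`nls` does not converge; non-convergence and non-identifiable inputs
(constant or all-zero series) are flagged in the result, never thrown.
R² is defined against the mean model, and the half-life is ln 2 / k
(k = 0.13 h⁻¹ ↔ 5.3 h). Units throughout: hours for time, per-hour for
rates, mole fractions for amplitudes.

## The synthetic-data generator

`simulate_timecourse()` emulates the extracted-intensity level of a
7-timepoint (0, 3, 6, 11, 24, 34, 48 h) direct-infusion FT-ICR-MS
labeling experiment. Each labeled subunit state follows a saturating
rise with optional onset lag, `b(1 − e^{−k·max(0, t − lag)})`, the
unlabeled state taking the closure remainder. The default scenario
reproduces the qualitative experimental picture: ribose rises fastest
(b = 0.93, k = 0.13 h⁻¹, no lag), glucose plateaus above 0.9 after a
10 h lag, and acetyl and the uracil states rise more slowly with lags
that grow with the number of 13C atoms, reflecting the longer reaction
chains. The generative kinetics are a parametric stand-in — the
underlying experiment publishes only fitted summaries, not raw
trajectories — so a green end-to-end test establishes that the pipeline
recovers parameters from data *of this form* at ~1% multiplicative
Gaussian noise (truncated at zero, rows renormalized), with natural
abundance convolved in when requested. It does not establish robustness
to features the generator lacks: non-Gaussian spike noise, correlated
channel drift, partial peak overlap, or model misspecification of the
subunit state sets themselves. The m17 channel produced by
natural-abundance convolution is truncated (observed tables carry
m0–m16) and the row renormalized; stripping remains exact because the
correction system is triangular from low mass upward.

Scenario seeds make datasets bit-reproducible, and the returned
ground-truth sidecar (scenario + seed) regenerates them exactly.

## Known limitations

* Only 13C natural abundance is corrected; multi-element correction
  matrices and resolution-dependent overlap are out of scope.
* No positional-isotopomer (NMR multiplet) modeling and no atom-mapped
  flux/EMU networks: deconvolution is at moiety level.
* The optimizer has no gradient-refinement stage; terminal accuracy is
  set by the annealing floor (1e-4 per move), i.e. ~1e-3–1e-4 per
  parameter at 1e5–1e6 steps.
* AIC-based selection assumes approximately Gaussian, homoscedastic
  residuals; intensity noise is multiplicative, so very large dynamic
  ranges would warrant a weighted objective, which the published target
  function does not use.
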