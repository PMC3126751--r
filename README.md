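# moietyfit

Moiety-based deconvolution of stable-isotope mass isotopologue
distributions.

## The problem

In stable isotope resolved metabolomics (SIRM), cells are fed a
13C-labeled substrate (typically [U-13C]-glucose) and the isotopologue
distribution of a metabolite — the mole fractions of species with
0, 1, 2, … heavy carbons — is read out by high-resolution mass
spectrometry. For a *modular* metabolite such as UDP-GlcNAc, built from
four biochemical subunits (glucose, 6 C; ribose, 5 C; acetyl, 2 C;
uracil, 4 C), each subunit is labeled through a different metabolic
route, so the subunit labeling fractions report on the fluxes of
glycolysis, the pentose phosphate pathway, the Krebs cycle and
pyrimidine biosynthesis — even far from isotopic steady state. But MS
only measures the total mass shift: the observed distribution is the
convolution of the subunit label distributions, and must be
deconvoluted.

`moietyfit` does that deconvolution for any metabolite declared as a
set of subunits with allowed 13C label counts:

* **Forward model.** With per-subunit state fractions (e.g. `g0 + g6 = 1`,
  `r0 + r5 = 1`, `a0 + a2 = 1`, `u0 + u1 + u2 + u3 = 1`), the predicted
  isotopologue intensity at mass shift *n* is
  `I_n = Σ (products of subunit fractions over joint states with total
  label n)` — the convolution of the subunit distributions. The default
  UDP-GlcNAc model has 32 joint isotopomers, 17 observable masses
  (m0–m16) and 6 free parameters.
* **Natural-abundance correction.** Raw intensities are stripped of
  natural 13C (binomial envelopes over the unenriched carbons,
  p ≈ 1.1%) and normalized to mole fractions.
* **GAIMS optimizer.** The free fractions are fitted by minimizing
  `T = Σ_n (I_n,obs − I_n,calc)²` with a hybrid simulated-annealing /
  genetic search (population 20, 5% crossover, 3 mutations per step,
  linear annealing, 10⁶ steps, 50 repeats for statistics).
* **Model selection.** Variant labeling models (e.g. allowing singly
  labeled acetyl) are generated from a grammar and ranked by AICc
  evaluated at the across-repeat mean parameters.
* **Kinetics.** Deconvoluted component timecourses are fitted to
  `b(1 − e^{−kt})` (rise) or `I(0)e^{−kt}` (decay), with half-life
  `ln 2 / k`.
* **Synthetic data.** A simulator with known ground truth emulates a
  7-timepoint FT-ICR-MS labeling experiment (0–48 h, ~1% intensity
  precision) so the whole pipeline is testable offline.

## Worked example

```r
library(moietyfit)

space <- udp_glcnac_space()
space
#> Moiety state space 'UDP-GlcNAc': 4 subunits, 17 carbons
#>   glucose     6 C  labels {0,6}  params {g0,g6}
#>   ribose      5 C  labels {0,5}  params {r0,r5}
#>   acetyl      2 C  labels {0,2}  params {a0,a2}
#>   uracil      4 C  labels {0,1,2,3}  params {u0,u1,u2,u3}
#>   32 isotopomers, 17 isotopologue masses, 6 free parameters

# simulate a labeling timecourse (1% noise, natural abundance included)
sim <- simulate_timecourse(default_scenario(seed = 7))

# correct one timepoint and deconvolute it
raw  <- as.numeric(sim$data[7, paste0("m", 0:16)])          # t = 48 h
prof <- normalize_profile(
  strip_natural_abundance(raw, correction_settings(17, 0.011)))
fit <- gaims_fit(prof, space,
                 gaims_settings(steps = 1e5, repeats = 10, seed = 1))
round(unclass(fit$best_params), 3)
#>    g0    g6    r0    r5    a0    a2    u0    u1    u2    u3
#> 0.083 0.917 0.072 0.928 0.690 0.310 0.181 0.185 0.484 0.151
round(sim$truth[7, ], 3)   # ground truth at 48 h
#>    g0    g6    r0    r5    a0    a2    u0    u1    u2    u3
#> 0.083 0.917 0.072 0.928 0.689 0.311 0.180 0.188 0.479 0.153

# kinetics of the labeled-ribose component across all timepoints
r5 <- vapply(seq_len(nrow(sim$data)), function(i) {
  raw <- as.numeric(sim$data[i, paste0("m", 0:16)])
  p <- normalize_profile(
    strip_natural_abundance(raw, correction_settings(17, 0.011)))
  st <- gaims_settings(steps = 2e4, repeats = 3, seed = i)
  unname(gaims_fit(p, space, st)$best_params["r5"])
}, numeric(1))
fit_exponential_rise(sim$data$time, r5)
#> rise fit: b = 0.927, k = 0.131 /h, R^2 = 1.000, t1/2 = 5.3 h
```

The recovered fractions say: by 48 h the glucose and ribose units are
>90% 13C-labeled (direct incorporation and pentose phosphate pathway),
the acetyl unit ~30% (diluted by unlabeled acetyl-CoA sources), and the
uracil ring is a mixture of 1-, 2- and 3-label states (scrambling
through the Krebs cycle); the labeled-ribose fraction rises with rate
k ≈ 0.13 h⁻¹, half-time ≈ 5.3 h.

(Fractions above are for the simulated dataset; outputs were printed by
the code shown.)

## Command line

```sh
Rscript exec/moietyfit simulate --seed 7 --out tc.tsv --truth truth.json
Rscript exec/moietyfit correct tc.tsv --carbons 17 --p13 0.011 --out corr.tsv
Rscript exec/moietyfit fit corr.tsv --steps 100000 --repeats 10 --seed 1 \
        --out params.tsv --report fit.json
Rscript exec/moietyfit select corr.tsv --seed 1 --out ranking.tsv
Rscript exec/moietyfit kinetics params.tsv --component r5 --form rise
```

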