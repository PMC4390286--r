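# sitegada

Subject-specific site index (height–age) modelling for stem-analysis data:
three base growth functions crossed with four parameterizations of the
tree-level parameters, with maximum-likelihood fitting, AICc model
comparison, and calibration of fitted models to new trees.

## The problem

Site index — the height of a dominant site tree at breast-height age 50 —
is the standard productivity measure in forest growth and yield work.
Stem analysis reconstructs each sample tree's full height–age trajectory,
giving repeated measurements per tree at breast-height ages 5, 10, 15, …
(growth time `t = bh_age − 0.5` years above breast height, heights in
metres above the 1.3 m datum).  Trees differ persistently, so every
workable model carries *local* (tree-specific) parameters next to the
*global* ones, and the scientific question is how to parameterize those
locals.  This package implements and compares four answers for each of
three base functions:

| base function | model |
|---|---|
| Chapman-Richards (CR) | `y = 1.3 + a0 (1 − e^{a1 t})^{a2}` |
| modified Hossfeld IV (HIV) | `y = 1.3 + (b0 t^{b1} / (b2 + t^{b1−1}))^{1/3}` |
| Schumacher (SCH) | `y = 1.3 + e^{c0 + c1 t^{c2}}` |

* **indicator variables** (`fit_indicator`) — free fixed-effect locals per
  tree, the flexibility benchmark;
* **nonlinear mixed effects** (`fit_mixed`) — Gaussian random effects with
  unstructured covariance, integrated out by a self-implemented marginal
  likelihood (Laplace, adaptive Gauss–Hermite, or first-order
  Beal–Sheiner);
* **GADA** (`fit_gada`) — locals replaced by functions of a growth
  intensity factor `χ` solved from an initial condition `(t0, y0)`,
  giving a base-age-invariant dynamic equation;
* **g-GADA** (`fit_ggada`) — one local drives the others through an
  explicit relation, either the GADA-equivalent one or a more flexible
  "optimal" relation chosen from local-parameter scatter plots.

Fits are compared by AICc (`−2ℓ + 2k + 2k(k+1)/(n−k−1)` with the profiled
Gaussian `−2ℓ = n[log(2πσ̂²)+1]`), estimated residual variance, and
age-binned error profiles.  `calibrate()` localizes a fitted model to a
new tree from one or more height–age pairs, with screening of multiple
roots.  Since no stem-analysis dataset is deposited, `simulate_trees()`
generates datasets with the study's structure (84 trees, protocol ages,
truncated-normal local laws linked by the optimal relation) for validation
and power studies.  The methods vignette
(`vignettes/site-index-parameterizations.Rmd`) documents the models,
numerical choices and generator in detail.

## Worked example

```r
library(sitegada)

trees   <- simulate_trees(sim_config(), seed = 20150408)
fit_ind <- fit_indicator(trees, "CR")
fit_gd  <- fit_gada(trees, "CR")
fit_opt <- fit_ggada(trees, "CR", "optimal")

fit_ind
#> <si_fit> CR site index model, indicator variables (locals: a0, a2)
#>   84 trees, 2763 observations
#>   globals: a1 = -0.00917644 (SE 0.000122)
#>   sigma2 = 0.2682, logLik = -2102.49, k = 170, AICc = 4567

comparison_report(fit_ind, fit_gd, fit_opt)
#>   parameterization     aicc    sigma2 pct_variance_increase
#> 1        indicator 4567.415 0.2682097               0.00000
#> 2    ggada_optimal 4833.428 0.3150172              17.45181
#> 3             gada 5235.014 0.3645793              35.93068
```

The free-locals indicator fit sets the benchmark (σ̂² = 0.268 m², close to
the generating noise 0.285 m²); the relation-constrained fits pay for
their parsimony with 17% and 36% variance increases — the qualitative
ordering the method comparison is about.  Calibrating the GADA model to a
single observed pair anchors the curve exactly through it:

```r
calibrate(data.frame(bh_age = 50, height = 14), fit_gd)
#> <si_calibration> CR (closed_form): chi0 = 3.8831
#>   1 observation(s); 1 candidate(s), 1 admissible
#>   site index (bh age 50): 14.00 m
```

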