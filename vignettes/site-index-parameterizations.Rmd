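---
title: "Subject-specific site index models: indicator variables, mixed effects, GADA and g-GADA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-specific site index models: indicator variables, mixed effects, GADA and g-GADA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitegada)
```

## The modelling problem

A site index model describes the height growth of free-growing dominant
trees as a function of age, and summarises site productivity by the *site
index*: the height reached at a reference (base) age, here breast-height
age 50.  Stem analysis reconstructs each sample tree's full height-age
trajectory, so a fitting dataset consists of repeated height measurements
per tree.  Height trajectories differ persistently between trees; any
credible model therefore needs *local* (subject-specific) parameters for
each tree alongside the *global* parameters shared by all trees.

Ages are ring counts at 1.3 m (breast-height age).  Growth above breast
height from age 0 to age 1 takes on average half a year, so the growth time
entering every model is `t = bh_age - 0.5`; heights are total heights in
metres and 1.3 m is a hard-coded datum, never a parameter.

Three three-parameter base functions are supported:

* Chapman-Richards (CR): `y = 1.3 + a0 (1 - exp(a1 t))^a2`, asymptote `a0`,
  rate `a1 < 0`, shape `a2 > 0`;
* modified Hossfeld IV (HIV):
  `y = 1.3 + (b0 t^b1 / (b2 + t^(b1-1)))^(1/3)`.  The `b1 - 1` exponent in
  the denominator (the modification relative to the classical Hossfeld IV)
  removes the asymptote: at old ages the curve grows like `(b0 t)^(1/3)`.
  `b0` still behaves approximately like an asymptote parameter;
* Schumacher (SCH): `y = 1.3 + exp(c0 + c1 t^c2)` with `c1 < 0`, `c2 < 0`
  and asymptote `exp(c0)`.

All residual errors are modelled as i.i.d. Gaussian with variance `sigma2`.

## Four parameterizations of the local parameters

**Indicator variables** (`fit_indicator()`): every local parameter takes a
free value per tree, estimated as a fixed effect.  No cross-tree assumption
is made, so this is the most flexible parameterization and the benchmark
the others are compared against.  The default local sets are the
asymptote-like and shape parameters (`a0, a2` / `b0, b2` / `c0, c1`),
leaving `a1`/`b1`/`c2` global.  Calibrating such a model for a new tree
needs at least one observation per local parameter.

**Nonlinear mixed effects** (`fit_mixed()`): the local parameters are
population draws, `a0_i = a0 + u0_i` etc., with `(u0, u2)` bivariate normal
with unstructured covariance.  The likelihood integrates the random effects
out tree by tree.  The package implements the marginal likelihood itself:

* *Laplace* (default): a second-order expansion at each tree's posterior
  mode, computed in standardized coordinates `u = L z` (`D = L L'`), where
  the expansion is well conditioned;
* *adaptive Gauss-Hermite* (`method = "agq"`): mode-centred,
  curvature-scaled quadrature (default order 9 per dimension).  It is the
  oracle the Laplace method is verified against and is exact in the linear
  sub-case;
* *first order* (`method = "first_order"`): the Beal-Sheiner linearization
  at zero random effects.  Lower fidelity, but kept because the HIV family,
  whose local parameters are strongly non-normal, often converges only this
  way; it is therefore the HIV default.

The per-tree posterior modes solve a penalized nonlinear least-squares
problem; they are found by a vectorized Levenberg-Marquardt Gauss-Newton
iteration with analytic Jacobians, all trees simultaneously.  The
covariance is parameterized by log standard deviations and an atanh
correlation, so proposals are positive semidefinite by construction, and the
reported marginal likelihood is invariant to that internal choice.

**GADA** (`fit_gada()`): two local parameters are replaced by functions of
an unobservable growth-intensity factor `chi` (CR: `a0 = exp(chi)`,
`a2 = a20 + a21/chi`; HIV: `b0 = b00 + chi`, `b2 = 0.5 b20 / chi`; SCH:
`c0 = c00 + chi`, `c1 = c10 + c11 chi`), and `chi` is solved from an
initial condition `(t0, y0)`, giving a self-referencing dynamic equation.
For CR and HIV the solution is the positive branch of a quadratic (the
negative branch is exposed via `root =` for screening); for SCH it is
linear.  The additive SCH constant `c00` is not identifiable jointly with a
per-tree `chi` and is fixed at zero.  During fitting `t0` is fixed (49.5 by
default, so each tree's `y0` is its site index and its observed height
nearest breast-height age 50 is the natural starting value) and the `y0`
are estimated as per-tree locals.  Because the equation is
self-referencing, the fitted curves and likelihood are invariant to the
choice of `t0`; this is checked in the test suite.

**g-GADA** (`fit_ggada()`): the growth-intensity factor is eliminated by
expressing the remaining local parameter(s) directly as functions of a
single driving local.  With `relation = "gada_equivalent"` the implied
relations above are substituted back, giving a model that is an exact
re-parameterization of the GADA model — same curves, same likelihood —
which the test suite verifies to optimizer precision.  With
`relation = "optimal"` the more flexible relations chosen from
indicator-variable local-parameter scatter plots are used: a quadratic of
`log(a0)` for the CR shape, an exponential and a linear function of `b0`
for the HIV `b1` and `b2`, and a log-linear function of `c2` for the SCH
`c0`.

## Maximum likelihood via profiling

All non-mixed fits share one engine.  For fixed globals, each tree's locals
minimize that tree's SSE independently, and the ML residual variance is
`SSE/n`; both are profiled out, so the outer optimization runs over only
the 1-4 globals.  Key numerical choices:

* One local per family (`a0`, `b0`, `exp(c0)`) enters the model linearly
  and is profiled in closed form; the remaining per-tree local is solved by
  a vectorized safeguarded Newton iteration over all trees simultaneously
  (finite-difference curvature, trust-region clipping, backtracking, a grid
  rescue for trees starting in an inadmissible region), warm-started across
  outer iterations.
* Locals and globals are optimized on transformed scales (log for
  positive, log of the negative for negative parameters) so every
  coordinate is O(1); the HIV `b2`, spanning several orders of magnitude,
  is handled by its log transform.
* The relation coefficients of the GADA/g-GADA models are nearly collinear
  in their natural basis (e.g. the quadratic in `log a0`).  The outer
  optimizer works in internal coordinates that centre each relation at the
  dataset's typical driving-local value, which makes the coordinates nearly
  orthogonal; estimates and standard errors are mapped back through the
  Jacobian.
* Quasi-Newton optimizers tend to stop with a measurable Newton decrement
  left on the long flat ridges these relations produce (the SCH relation
  slope is the worst case, because the per-tree `c0` span is narrow).  After
  `nlminb`, the engine polishes with explicit damped (Marquardt) Newton
  steps using its own finite-difference gradient and Hessian, and declares
  convergence only when the Newton decrement of the profiled likelihood is
  negligible (< 1e-3), not from the optimizer's return code.
* Multi-start: the first start comes from data-driven heuristics (per-tree
  log-scale regressions give rough locals; regressing those locals on each
  other per the assumed relation seeds the relation globals); the default 4
  extra jittered starts are screened with short runs and only polished when
  they beat the incumbent.  Every stochastic element (the jitter) uses an
  explicit seed (`si_control(seed = )`, default 20150408) and restores the
  global RNG state.
* Inadmissible parameter combinations met during the search are penalized
  (large finite objective), never fatal.
* Standard errors come from the curvature of the profiled likelihood,
  computed in the well-conditioned internal coordinates and mapped to the
  natural scale; profiling leaves these curvatures identical to the
  corresponding blocks of the full-parameter information.

AICc is `-2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `-2 logLik` in the
profiled Gaussian form `n (log(2 pi sigma2_hat) + 1)`.  Parameter counts:
indicator fits count globals + locals x trees + 1 (variance); GADA counts
3 + trees + 1; g-GADA counts its relation globals + trees + 1; mixed fits
count fixed effects + free covariance entries + 1, with the per-tree
empirical-Bayes values treated as predictions, not parameters.  These
conventions exactly reproduce the published AICc values of all nine
reconstructable fits (see `tests/testthat/test-acceptance.R`).  The
variance of a fit is reported with the large-sample standard error
`sigma2 * sqrt(2/n)`, and fits are compared by AICc, variance (with
percentage increase over the indicator benchmark), and age-binned error
profiles (5-year bins matching the measurement protocol; the zero-mean test
is a two-sided one-sample t-test at alpha = 0.05, a choice this package
makes since the source analyses do not name their test).  Fits on different
datasets are never compared: removing hard trees lowers AICc and variance
spuriously.

## Calibration

Applying a fitted population model to a new tree means estimating its local
parameter(s) from one or more observed height-age pairs
(`calibrate()`):

* GADA, one pair: the closed-form `chi0` anchors the curve exactly through
  the point.
* GADA, several pairs: least squares over `y0`.
* g-GADA: a one-dimensional least-squares problem in the driving local.
  The search evaluates a dense grid across the admissible range, polishes
  every local minimum (and, for a single point, refines by a root solve of
  the anchoring equation to machine precision), and keeps *all* candidates:
  multiple roots are real and the wrong one is usually revealed by an
  inadmissible value.  `screen_roots()` rejects candidates outside the
  admissible local ranges observed in fitting
  (`a0` in [12.1933, 58.3228], `b0` in [63.5669, 433.68],
  `c2` in [-0.6133, -0.2371]) or producing inadmissible curves, and breaks
  ties by the smallest calibration residual.
* Indicator: per-tree least squares; requires at least one observation per
  local parameter.
* Mixed: the empirical-Bayes posterior mode of the random effects
  (`predict_random_effects()`), usable from a single pair, with the
  posterior covariance reported so the user can see how weakly one point
  constrains an asymptote.  Calibrated HIV parameters are always
  admissibility-checked: large negative random effects can make the curve
  undefined.

Calibration observations follow the same `t = bh_age - 0.5` convention.
Converting total age to breast-height age requires the tree's years to
breast height, which this package does not estimate.

## The synthetic-data generator

No stem-analysis dataset ships with the package, so `simulate_trees()`
generates datasets with the structure the analysis assumes: 84 trees by
default; per-tree maximum breast-height age uniform on {70, 75, ..., 255};
heights at the protocol ages 5, 10, 15, ...; i.i.d. Gaussian height noise.
The default local-parameter law draws the driving local from a truncated
normal (CR `a0`: mean 32 m, SD 7 m, truncated to the admissible
[12.19, 58.32]; chosen so that site indices centre near 12 m and the height
span stays within roughly 8-41 m over the age span), derives the partner
parameter through the optimal g-GADA relation, and adds Gaussian scatter
(default SD 0.08 on the CR shape, and family-scaled equivalents) so the
locals do not sit exactly on any one relation.  That scatter is what gives
the free-locals indicator fit a genuine advantage and reproduces,
qualitatively, the observed ordering indicator < mixed < optimal g-GADA <
GADA in residual variance.  Matched laws (`parameterization = "gada"`,
`"ggada_optimal"`, `"mixed"`) generate data exactly from the corresponding
model structure for estimator-calibration studies.  All laws use the
measurement-scale noise variance 0.285 m^2 by default: the much larger
residual variances realised by fitted GADA-family models (~1.2 m^2)
include cross-tree relation lack-of-fit and are not noise levels -- used
as Gaussian noise they would collide with the 1.3 m height floor at young
ages and bias the rate parameter.  The GADA law
draws each tree's site index from N(12.5, 2.5^2) m truncated to [6, 20].

Noise draws that would place a height below the 1.3 m datum are re-drawn
(a tree with positive breast-height age is taller than breast height by
definition); this slightly truncates the noise distribution at the youngest
ages.  Subzone labels are attached as grouping metadata only, with
frequencies proportional to the sampling summary in `essf_subzones()`; no
subzone effects are simulated.

What passing tests on these data do show: correctness of the likelihoods,
the algebra, the optimizers and their standard errors under the stated
error model.  What they cannot show: robustness to serially correlated
height residuals, suppression and damage episodes, measurement error in
pith-node location, or non-normal local-parameter distributions — all
present in real stem-analysis data.  In particular the mixed-model
assumption of Gaussian locals is exactly true here, whereas for real data
the HIV locals are strongly skewed (use `normality_diagnostic()`).

## Problem sizes used in validation

The test suite fits 84-tree datasets (~2700 observations) for the
acceptance-level checks — the equivalence of GADA and g-GADA fits per
family, and a 20-replicate coverage study of 2-SE intervals for the
indicator, GADA, optimal g-GADA and mixed CR fits (single-start fits from
the data-driven heuristics, which on matched simulations converge without
multi-start) — and smaller 3-30-tree datasets for unit-level oracles:
brute-force multi-start likelihood comparison, closed-form Gaussian
marginals, grid quadrature, and calibration round-trips.  The same
computations, at the same sizes, are re-run by `scripts/acceptance.R`.

## Known limitations

* Indicator fits support at most two nonlinear locals per tree plus the
  closed-form scale local.
* The SCH relation slope (`c11`) is weakly identified when the per-tree
  `c0` spread is narrow; its standard error is honest (large), but
  optimizer agreement between the GADA and g-GADA forms is then limited by
  the flatness of the ridge (likelihoods agree to ~1e-6, coefficients along
  the ridge to ~1e-4 relative in our checks).
* The mixed-effects implementation supports one or two random parameters
  per tree.
* First-order (Beal-Sheiner) marginal likelihoods are biased when random
  effects are large; they are reported as their own `method` and never
  silently mixed with Laplace/AGQ results.
* Model comparison assumes the same observation set; the package refuses
  cross-dataset comparisons rather than footnoting them.
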