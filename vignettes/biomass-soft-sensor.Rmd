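---
title: "Methods: a cOUR-driven biomass soft sensor for fed-batch cultures"
author: "coursense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cOUR-driven biomass soft sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coursense)
```

## The estimation problem

Aerobic fed-batch cultivations consume oxygen for two purposes: building new
biomass and maintaining the biomass that already exists (which, after
induction of a recombinant product, also covers product synthesis). The
Luedeking–Piret balance separates the two:

$$\mathrm{OUR}(t) = \alpha\,X'(t) + \beta\,X(t),$$

with $\alpha$ the specific oxygen yield for growth (g O₂ per g DCW) and
$\beta$ the maintenance coefficient (h⁻¹ scale). OUR is noisy; integrating
it from inoculation into the cumulative uptake cOUR both filters the noise
and correlates directly with accumulated biomass:

$$\mathrm{cOUR}(t) = \alpha\,(X(t) - X_0) + \int_{t_0}^{t}\beta\,X\,dt^{*}.$$

Everything in this package is built around this identity: Stage A inverts it
for the stoichiometric parameters using sparse offline DCW samples, Stage B
inverts it for $X$ online using the identified parameters.

## Stage A: offline identification

### Two parameterisations of maintenance

$\beta$ is not constant: it is negligible during lag/early exponential
growth and grows once biomass (or induced product synthesis) is
appreciable. During *fitting* we use the time-linear form

$$\beta(t) = \max\{0,\; k_1 (t - t_i)\},$$

because it keeps the criterion quadratic in the unknowns. For *online use*
the time origin of a future culture is meaningless, so Stage A converts the
fitted $\beta(t_m)$ values into a biomass parameterisation
$\beta(X) = k_{\beta2}X^2 + k_{\beta1}X + k_{\beta0}$ by ordinary
least-squares regression against the observed $X_m$ — quadratic for
*E. coli*-like strains, linear for yeast-like ones. Both forms are clamped
at zero: negative maintenance would credit oxygen back, which is
unphysical.

### The weighted criterion and its closed form

With offline samples $X_m$ at times $t_m$ and matched observations
$\mathrm{cOUR}_m$, the model prediction is

$$\widehat{\mathrm{cOUR}}_m = \alpha\,(X_m - X_0) + k_1 R_m,\qquad
R_m = \sum_{l \le m,\; t_l > t_i} (t_l - t_i)\,X_l\,\Delta t_{l,l-1},$$

a right-endpoint rectangle sum over the offline grid (the first interval is
measured from inoculation). The fit maximises the entropy criterion

$$S = -\sum_m w_m\,(\mathrm{cOUR}_m - \widehat{\mathrm{cOUR}}_m)^2,
\qquad w_m = \frac{K_{exp} X_m^2 + (1 - K_{exp})}{X_m^2},$$

whose weights are the reciprocal of a Monod-form variance model
$\sigma^2_m \propto X_m^2/(1 - K_{exp} + K_{exp}X_m^2)$: measurement
uncertainty grows with the signal but saturates. $K_{exp}=1$ recovers
ordinary least squares, $K_{exp}=0$ recovers variance $\propto X^2$
(squared-percentage-error weighting); the default 0.4 is the published
compromise that worked across both cultures. $S \le 0$ with equality only
at a perfect fit, and it is quadratic in $(\alpha, k_1)$, so the maximiser
solves a 2×2 linear system assembled in one pass over the samples
(`solveStoichiometry()`); no iterative optimisation, no starting values, no
convergence issues.

Two index conventions needed resolving:

* The published sums for the maintenance regressor are ambiguous about
  their lower index; we include only terms with $t_l > t_i$. Including
  earlier terms would multiply by negative $(t_l - t_i)$ factors, i.e.
  negative maintenance before activation.
* The discretization is named a "left Riemann sum" in the literature this
  implements, but the printed formula evaluates the integrand at the right
  endpoint of each subinterval; we follow the formula, and use the same
  rule in `cumulativeOUR()` so all three stages share one discretization.

### Activation time search

For *E. coli* the activation time is the known IPTG injection and is used
directly. For yeast it is inferred: `findInductionTime()` evaluates the
closed-form solution and its criterion at every candidate (default: the
offline sample times after the first) and keeps the maximiser. The search
is exhaustive rather than a continuous convex optimisation: with at most a
few dozen offline samples it is exact on the grid and costs microseconds.
Ties — including the completely flat criterion of single-phase data, where
any candidate fits perfectly — resolve to the *earliest* candidate (within
a floating-point tolerance scaled by the criterion's natural magnitude
$\sum_m w_m \mathrm{cOUR}_m^2$), which activates maintenance conservatively
early; if no sample follows the chosen time, the fit is flagged
"maintenance unidentifiable" and $k_1 = 0$.

### The biomass threshold $X_{specific}$

The online estimator switches maintenance on above the biomass
concentration at which $\beta(X) = 0$. For the linear model that is the
root $-k_{\beta0}/k_{\beta1}$ (6.29 g/l for the published yeast line). For
the quadratic we take the real root at which $\beta$ *turns positive with
increasing biomass*: the larger root of a convex parabola, the smaller root
of a concave one. (The naive "largest root" rule misbehaves for concave
fits, whose largest root is where maintenance *ends*.) Two degenerate cases
are handled explicitly:

* **Negative discriminant** — the published *E. coli* parabola never
  crosses zero; the threshold falls back to the stationary point
  $-k_{\beta1}/(2k_{\beta2})$ (20.6 g/l) and is flagged. This mirrors the
  published threshold, which coincides with that stationary point.
* **No positive root under noise** — a fitted line already positive at
  $X \to 0$ means maintenance was observed over the whole sampled range;
  `fitStrain()` then anchors the threshold at the smallest post-activation
  biomass sample and flags the fit, rather than failing.

`fitStrain()` additionally downgrades a concave ($k_{\beta2} < 0$)
quadratic to the linear model: maintenance demand that eventually *falls*
with biomass is physically implausible and, in practice, an artefact of
noise or of the time-to-biomass conversion.

### Pooling replicate experiments

A strain is fitted once from all its experiments: each experiment is solved
separately, per-experiment $\alpha$ (and $k_1$, $t_i$) are combined by a
precision-weighted mean using the Gram weight $B = \sum_m w_m (X_m-X_0)^2$
of each solve, and the $(X_m, \beta(t_m))$ pairs are pooled into a single
maintenance regression. Fitting three identical replicates therefore
returns exactly the single-experiment result.

## Stage B: online estimation

Given strain parameters, the estimator needs the cOUR stream and the
inoculation biomass $X_0$ (directly, or as optical density × 0.4 g/l per
o.u.). Below the threshold,

$$X_m = \mathrm{cOUR}_m/\alpha + X_0;$$

above it the accumulated maintenance oxygen is removed first,

$$X_m = \bigl(\mathrm{cOUR}_m - \textstyle\sum_{l<m}\beta(X_l)X_l\Delta t\bigr)/\alpha + X_0,$$

with the sum advanced by the *previous* estimate (each point is computed
once and never revisited — the property that keeps the estimator O(1) per
update). Numerical policies, all observable in `updateEstimate()`:

* the regime switch latches: once above $X_{specific}$ the estimator never
  switches back, avoiding chattering when the trajectory hovers near the
  threshold;
* a decreasing cOUR stream (sensor glitch) beyond 1e-6 g/l triggers a
  data-quality warning but the value is used as-is; non-monotone *time* is
  a hard error;
* negative estimates (possible under heavy noise at low signal) are floored
  at zero with a warning.

Because the maintenance sum uses the previous-point rule, the method's
intrinsic discretization error is first order in the sampling interval; the
tests verify the error shrinks ~10× from a 10-min to a 1-min grid and
again to a 6-s grid. One-minute sampling — the norm for off-gas analyzers —
keeps the noise-free round-trip error around 0.01% MAPE.

## The synthetic-data generator

No cultivation datasets are deposited with the originating study, so the
simulator defines the study conditions used by every test:

* **Growth law**: $X' = \mu(t)X$ with $\mu = \mu_{max}$ until induction and
  $\mu = \mu_{max}e^{-d(t-t_i)}$ afterwards — the simplest shape producing
  a lag/exponential phase followed by deceleration with appreciable
  maintenance. Defaults: $\mu_{max} = 0.35$ h⁻¹, $d = 0.15$ h⁻¹,
  $X_0 = 0.2$ g/l, induction at 10 h, 20 h duration; the default culture
  crosses the *E. coli* threshold (20.6 g/l) around 14 h and reaches
  ~40 g/l, matching the operating range the published experiments report.
* **Trajectory evaluation** is by the closed form
  $X = X_0 e^{\int\mu}$ (the integral of $\mu$ has an elementary
  antiderivative), so the truth carries no integration error. Explicit
  Euler stepping at a 1-min grid would already contribute ~0.4% drift over
  5 h at $\mu = 0.3$ — larger than the estimator errors being measured.
* **OUR** comes from the forward balance with either maintenance
  parameterisation ($\beta(t)$ to exercise Stage A in exactly the form it
  fits; $\beta(X)$ to exercise Stage B). The growth term uses the
  interval-mean rate $\Delta X/\Delta t$, what an interval-averaging gas
  analyzer reports; the growth part of cOUR then telescopes exactly and
  only the maintenance quadrature is discretized.
* **Noise** is multiplicative Gaussian on observed cOUR and offline DCW
  (truth untouched, seed mandatory), defaults 2% and 5% CV. Optionally the
  cOUR noise follows the Monod-form variance structure the Stage A weights
  assume.
* **`simulateStageAExperiment()`** generates observations *on the offline
  grid with the estimator's own discretization*, so noise-free Stage A
  recovery is exact to machine precision — this isolates estimation error
  from discretization mismatch. The dense-grid `simulateCulture()` output,
  whose hourly offline samples do not share the estimator's maintenance
  discretization, is the harder, realistic case.

What the simulator does *not* emulate: substrate/feed mass balances,
dissolved-oxygen dynamics, CO₂ signals, broth-weight changes, sensor drift
or dropout, and metabolic shifts (overflow metabolism, diauxie). Passing
tests therefore demonstrate correctness of the identification and
estimation machinery under the model's own assumptions, not robustness to
every real-culture artefact.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `kExp` | – | 0.4 | uncertainty-weighting exponent; 1 = OLS, 0 = %-error weighting |
| `degree` | – | 2 | maintenance polynomial degree (auto-downgrade if concave) |
| `inductionTime` | h | data | known activation time; absent → criterion search |
| OD factor | g/l per o.u. | 0.4 | optical density → DCW conversion |
| online interval | h | 1/60 | cOUR sampling; estimator error is first order in it |
| offline interval | h | 1 | DCW sampling cadence of the synthetic harness |

## Problem sizes in the test suite

The suite runs 20-hour cultures at a 1-min online grid (1201 points) with
hourly offline sampling (20 samples); the grid-refinement checks use 10-min
and 6-s variants; the brute-force criterion oracle covers 50 random
instances of ≤ 12 samples; the noisy recovery studies use 20 fixed seeds
(Stage A) and 10 seeds (Stage B). These sizes were chosen so the whole
suite exercises every code path in well under a minute of compute while
keeping Monte Carlo margins comfortable.

## Known limitations

* cOUR must be computed upstream from off-gas O₂/CO₂ fractions and gas
  flow; that conversion is instrument-specific and out of scope here.
* $\alpha$ is assumed constant per strain across the whole culture;
  metabolic shifts violate this and appear as bias, not as a warning.
* The separation of maintenance into cell upkeep vs product formation is
  not identifiable from cOUR alone; only their sum $\beta$ is estimated.
* Confidence intervals on the fitted parameters are not produced; the
  published intervals for the reference strains come with no stated method.
* The activation-time search is exact only on its candidate grid; with the
  default grid (offline sample times) $t_i$ resolves to the sampling
  cadence, which is also the accuracy limit of the data.
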