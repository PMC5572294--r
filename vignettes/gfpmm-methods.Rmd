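---
title: "Fractional-polynomial mixed models for binary and count panels: models, estimation, and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-polynomial mixed models for binary and count panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfpmm)
```

## The modeling problem

Longitudinal studies in the behavioral and health sciences routinely collect
binary or count outcomes at a handful of waves per subject: an at-risk
indicator at ages 3, 8, 12 and 17, or a test score measured three times six
months apart.  Two features dominate such data: the mean trend over time is
often non-linear and asymmetric, and subjects differ persistently from one
another.  Conventional polynomials handle the first feature poorly — they are
symmetric around their vertices and pay one parameter per wiggle — while
ignoring the second feature biases every inference.

This package couples a **fractional polynomial (FP)** time transformation
with a **generalized linear mixed model (GLMM)**.  The linear predictor for
subject $j$ at time $t_{ij}$ is

$$
\eta_{ij} \;=\; \beta_0 + \sum_{b=1}^{p}\beta_b\, f_b(t_{ij})
 + \sum_{e=1}^{l}\gamma_e X_{ej}
 + b_{0j} + \sum_{g=1}^{q} b_{gj}\, f_g(t_{ij}),
\qquad \mathbf{b}_j \sim N(\mathbf 0, \Psi),
$$

with $g(\mu_{ij}) = \eta_{ij}$ for a logit (binary) or log (count) link.
The FP terms $f_b$ are built from the Box–Tidwell transform
$t^{(m)} = t^m$ for $m \ne 0$ and $\log t$ for $m = 0$, with powers drawn
from the Royston–Altman set

$$
M = \{-2, -1, -0.5, 0, 0.5, 1, 2, \max(3, m)\},
$$

and a repeated power $m_h = m_{h-1}$ generating the term
$f_h = f_{h-1}\cdot\log t$.  Eight powers at order one already span shapes
from sharp early decay ($m = -2$) to late acceleration ($m = 3$); power 1
reproduces the conventional linear model exactly, which the test suite
asserts as an identity.

All transforms require $t > 0$.  The package rejects non-positive times and
suggests the affine pre-scaling $t \mapsto (t - a)/c$; the bundled presets
(ages 3–17, waves 1–3) need none.

## Estimation: Laplace maximum likelihood

The marginal likelihood integrates the conditional density over the random
effects,

$$
L(\beta, \Psi) = \prod_j \int p(y_j \mid \beta, \mathbf b)\,
  \phi(\mathbf b; 0, \Psi)\, d\mathbf b ,
$$

which has no closed form for binomial or Poisson responses.  `fit_gfpmm()`
maximizes the **Laplace approximation**: for each subject the joint
log-density is maximized over $\mathbf b$ (damped Newton, implemented in
C++), and the curvature correction
$-\tfrac12 \log\det(I + \Psi Z_j' W_j Z_j)$ is added at the mode
$\hat{\mathbf b}_j$.  Both families are canonical-link with dispersion fixed
at 1, so the joint is strictly concave in $\mathbf b$ and the inner Newton is
globally convergent.

Numerical choices that matter, all fixed and deterministic:

* **Inner stopping rule.** Iterations stop when the gradient norm falls
  below $10^{-8}$ *or* the Newton decrement $g' H^{-1} g$ falls below
  $10^{-15}$.  The decrement is scale-invariant; an absolute gradient rule
  alone is unattainable in floating point when a variance component is near
  zero and $\Psi^{-1}$ entries reach $10^9$ or more.
* **Stable determinant and quadratic form.**  The correction is evaluated as
  $\log\det(I + L' M L)$ with $L$ the lower Cholesky factor of $\Psi$
  ($M = Z'WZ$); since $L'ML$ is positive semi-definite every term of
  $1 + \mathrm{tr} + \det$ is non-negative.  The prior quadratic form is
  evaluated as $\lVert L^{-1}\mathbf b\rVert^2$.  The naive forms suffer
  catastrophic cancellation when the intercept–slope correlation approaches
  $\pm 1$, a region the optimizer must be able to traverse.
* **Parameterization.** $\Psi$ is optimized through its log-Cholesky factor
  (diagonal on the log scale, floored at $10^{-10}$), which enforces positive
  semi-definiteness without constraints; a fit at the floor is flagged as a
  boundary fit.  The intercept–slope covariance is estimated freely — this is
  what makes a random-slope model carry 3 covariance parameters and hence
  the familiar df = 5 / df = 6 accounting.
* **Column scaling.** Non-intercept design columns are internally divided by
  their maximum absolute value ($t^3$ reaches 4913 by age 17); estimates,
  standard errors and $\hat\Psi$ are reported back on the original scale.
* **Outer optimizer.** Derivative-free BOBYQA from three fixed starting
  factors ($0.5 I$ and two asymmetric small-variance variants), followed by a
  quasi-Newton polish with central-difference gradients; the best objective
  wins, and a polish round that can no longer improve the objective beyond
  $10^{-8}(1 + |\ell|)$ counts as converged.  The profile surface is
  extremely flat along the log-Cholesky directions whenever a variance is
  small or the correlation saturates, and single-start gradient methods can
  stall there or collapse the intercept variance into a wrong basin; the
  fixed multi-start is cheap insurance and keeps the fit fully
  deterministic — refitting the same panel is bit-identical, which the test
  suite asserts.
* **Standard errors.** From the inverse observed information of the Laplace
  objective in the $\beta$ block, with $\Psi$ held at its estimate;
  uncertainty in $\Psi$ is not propagated.

`information_criteria()` uses $n$ = total observations (the dominant
mixed-model software convention) in
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ and
$\mathrm{BIC} = -2\ell + k\log n$.

### The quadrature reference

`agq_loglik()` evaluates the same marginal likelihood by adaptive
Gauss–Hermite quadrature: nodes centered at each subject's conditional mode
(found by an independent optimizer, then Newton-refined) and scaled by the
joint curvature.  One node reproduces the Laplace value to $10^{-10}$ — an
algebraic identity the tests assert — and increasing nodes converges to the
exact likelihood.  The evaluator is the package's accuracy reference; the
production fitter never calls it.  The Laplace error grows roughly like
$\sigma^4$ for binary panels: about $10^{-3}$ at $\sigma = 0.1$, a few
hundredths of a log-likelihood unit at $\sigma = 1$ with four observations
per subject.  The property tests that compare the two evaluators therefore
draw instances with $\sigma \le 0.1$, the regime the quadratic expansion is
designed for; the systematic attenuation at strong heterogeneity is a known
property of Laplace estimation for binary data and is documented under
limitations below.

## The penalized-spline trend diagnostic

Before any parametric search, `fit_trend_gam()` fits
$g(E(Y)) = s(t)$ by penalized IRLS with a cubic B-spline basis (default 10
functions; interior knots at time quantiles, falling back to equal spacing
when a handful of waves makes quantile knots collide) and a second-order
difference penalty.  The smoothing parameter minimizes the GCV score
$n D / (n - \mathrm{tr}\,H)^2$ over 40 log-spaced values from $10^{-4}$ to
$10^8$.

Two effective-degrees-of-freedom conventions coexist in practice, so the
object stores both: `edf` is the full influence trace $\mathrm{tr}\,H$
(bounded by the penalty null space, 2, below and the basis dimension above —
both limits are asserted in tests), while `edf_smooth = edf - 1` discounts
the constant level, matching the convention in which "an edf of one" means
an essentially linear trend.  The diagnostic is strictly advisory: it prints
an edf and a shape hint and never constrains the candidate set, mirroring
how such smooths are used in practice (a linear-looking smooth can coexist
with a decisively non-linear parametric winner).

## Model selection

`run_selection()` stages the comparison-table workflow:

1. advisory GAM diagnostic;
2. **conventional class (GCPMM)**: degrees up to (waves − 2) — a cubic on
   four waves would saturate the fixed effects — with random intercept then
   random slope, GLRT-tested along the ladder RI-linear → RI-quadratic →
   RS-linear → RS-quadratic, each model against its most recent *nested*
   predecessor;
3. **FP class (GFPMM)**: all eight first-order powers (order 2 on request:
   36 power pairs) crossed with the random structures, compared by
   $\Delta$AICc/$\Delta$BIC over the full candidate set;
4. **covariate stage**: each static covariate GLRT-tested at 0.05 on the
   best model of each class; its time interaction is tested only if the main
   effect is retained (the well-formulated rule);
5. **cross-class**: best GCPMM vs best GFPMM by deltas only.

GLRTs between non-nested models are refused and the refusal is logged:
a likelihood ratio between non-nested models has no $\chi^2$ reference
distribution, so cross-class tables leave the GLRT cell blank rather than
print a degenerate statistic.  Nesting is checked structurally (fixed terms
a subset, random structure no richer, slopes on the same transformed term).

Support categories follow the $\Delta \le 2$ (substantial),
$4 \le \Delta \le 7$ (considerably less), $\Delta > 10$ (essentially none)
convention; the unnamed gaps $(2,4)$ and $(7,10]$ are labeled
"intermediate".  Deltas are computed over the full displayed candidate set
of each table.  Best-by-BIC and best-by-AICc are always reported separately
and never silently merged; ties break toward fewer parameters, then toward
the conventional class.  The lead criterion is configurable; AICc is the
default lead for the final recommendation, while the selection-recovery
study below uses BIC, which is the selection-consistent choice when the true
model is in the candidate set — at $n \approx 6000$ observations AIC-type
criteria tolerate one superfluous parameter per ~2 log-likelihood units,
which is exactly the regime where a quadratic-plus-extra-parameter can edge
out the true cubic by chance.

## What the simulators emulate

`cls_sim_config()` builds a binary four-wave panel (ages 3, 8, 12, 17;
1,539 subjects) whose marginal at-risk proportions track
0.729 / 0.652 / 0.639 / 0.535.  Random effects attenuate marginal means, so
a two-parameter cubic trend cannot hit four arbitrary proportions;
`calibrate_intercepts()` therefore solves, per wave, for the offset whose
31-node Gauss–Hermite integral of the inverse link over
$N(0, z'\Psi z)$ equals the target (monotone bisection, tolerance $10^{-8}$).
The preset's covariance (intercept s.d. 1 logit; slope s.d. $2\times10^{-4}$
on the $t^3$ scale, correlation −0.2) produces visible but modest
between-subject trend variability.

`rmet_sim_config()` builds a three-wave Poisson panel (212 subjects, waves
coded 1–3 so no rescaling is needed) with an FP power-2 declining trend,
a gender code drawn as 1 (girl) / 2 (boy) with a positive log-scale
coefficient of 0.15 — girls' mean lower — and a correlated random intercept
and slope.  No published mean counts or variance components exist for this
setting, so these values are conventions chosen to make a small count panel
with a gender effect near the detection boundary; nothing downstream depends
on them numerically.

Two further generating configurations are fixed in the test helpers:

* the **parameter-recovery study** (50 replicates, $N = 500$, cubic power,
  random slope) uses moderate heterogeneity — intercept s.d. 0.5, slope
  s.d. $5\times10^{-5}$ — where the Laplace expansion is accurate, so the
  study isolates finite-sample error of the estimator rather than
  approximation bias;
* the **selection-recovery study** (20 replicates, $N = 1500$) uses a
  pronounced flat-then-drop cubic trend (a 3.5-logit conditional drop,
  90% of it after the third wave) with slope heterogeneity sized so the true
  model's dominance matches the magnitudes a real risk panel shows: the
  runner-up FP power trails by $\Delta$BIC ≈ 25, the conventional quadratic
  by ≈ 40, and random-intercept variants by > 100.

Covariates, random effects and responses are drawn from one seeded stream in
a fixed order, so every panel is exactly reproducible from its
configuration; panels are not invariant under a change of subject count.

What passing these simulations does *not* show: real risk panels have
missing waves, informative dropout, within-wave dependence and covariate
measurement error, none of which the generators emulate.  The studies
validate the machinery — transforms, likelihood, selection logic — under the
stated conditions, not the scientific conclusions one would draw from any
particular dataset.

## Degenerate inputs and edge cases

Non-positive times are rejected with a rescaling hint.  Binary responses
outside $\{0,1\}$ and non-integer counts are errors naming the offending
rows; missing responses are dropped with a logged count.  A rank-deficient
fixed design names its collinear columns.  A random structure with as many
dimensions as subjects is refused as unidentifiable.  $\Psi \to 0$ reduces
every evaluator to the fixed-effects GLM log-likelihood, and marginal
prediction collapses to conditional prediction exactly.

## Problem sizes in the test suite

The suite fits panels between 3 and 20,000 subjects.  The heavier studies —
50-replicate parameter recovery at $N = 500$, 20-replicate selection
recovery at $N = 1500$, a 100-replicate GLRT null-rate band at $N = 250$ —
were sized to exercise each property at meaningful scale while keeping any
single study in the minutes range on one core; the full suite runs in about
ten minutes.

## Known limitations

* Random-effect dimension is capped at two (intercept + one slope), matching
  the model class; no crossed or nested grouping factors.
* Laplace ML attenuates estimates for binary panels with strong
  heterogeneity (intercept s.d. $\gtrsim 1$ with few waves); the quadrature
  evaluator quantifies the gap but is not used for fitting.  No REML-type
  correction is applied.
* Standard errors ignore $\Psi$ uncertainty (observed information, $\beta$
  block only).
* The discrete power set is searched exhaustively; powers are never
  estimated by continuous optimization, and FP transforms apply to time
  only, not to other covariates.
* No dropout or missing-data mechanisms; rows with missing responses are
  simply dropped.
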