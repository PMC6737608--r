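---
title: "Attributable fractions from case-control data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions from case-control data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paftools)
```

This vignette is the package's account of its statistical content: the
model, the estimators, the approximation the graphics are built on,
and the design decisions that were genuinely open.

## Model and identification

For binary outcome $Y$, exposure $A$ with reference level $0$ and
confounders $C$, everything rests on the logistic disease model

$$\operatorname{logit} P(Y=1 \mid A=j, C=c) = \mu + \beta_j + \gamma(c),$$

with $\beta_0 = 0$ (for continuous exposures, a curve $\beta(j)$
anchored at a minimum-risk value $j_0$).  The target is the
counterfactual population attributable fraction

$$\mathrm{PAF} = \frac{P(Y=1) - P(Y^{a=0}=1)}{P(Y=1)},$$

the proportional drop in disease prevalence if everyone were moved to
the reference exposure.  Identification needs the standard trio —
consistency, positivity, conditional exchangeability given $C$ — plus
two modelling assumptions baked into the formula layer:

* **no interaction**: the relative risk comparing exposure levels does
  not vary across confounder strata (the additive $\beta_j$ above);
* **rare disease**: outcome probability small in every stratum, so the
  odds ratios a case-control study estimates stand in for relative
  risks.

Under these, the PAF is estimable from case-control data alone as the
case-side plug-in ("exact") estimator

$$\widehat{\mathrm{PAF}} = \sum_{j\ge 1} \hat P(A=j \mid Y=1)\,
  \frac{e^{\hat\beta_j}-1}{e^{\hat\beta_j}},$$

implemented in `exact_paf_discrete()` and, with sums replaced by means
over the case sample, `exact_paf_continuous()`.  `paf()` wires the
logistic fit, the empirical exposure distributions and these formulas
together behind a formula interface (first right-hand-side term =
exposure, the rest confounders).

## The approximation and the averaged log-odds ratio

A first-order expansion of the exact estimator in the log-odds ratios
gives the multiplicative approximation

$$\mathrm{PAF}_a = \hat P \,\hat\beta^{\,\mathrm{ave}},\qquad
  \hat\beta^{\,\mathrm{ave}} = \frac{\sum_{j \ge 1}\hat P(A=j\mid Y=0)
  \hat\beta_j}{1-\hat P(A=0\mid Y=0)},$$

with $\hat P$ the control-side prevalence of any non-reference level.
For binary exposures $\hat\beta^{\,\mathrm{ave}}$ is simply the fitted
log-OR, which makes `approx_paf()` a handy rule of thumb for
converting logistic regression coefficients into attributable
fractions.  For continuous exposures the averaging integral runs over
the whole control density, so the conventional prevalence is 1 and
$\hat\beta^{\,\mathrm{ave}}$ itself absorbs the prevalence factor; a
two-point continuous exposure therefore reproduces the binary
*approximate PAF* exactly while its raw average is the binary log-OR
scaled by the prevalence.  The unit-tests assert exactly these
identities.

Three deliberate conventions:

* all log-odds ratios are natural logs throughout the computation
  layer; base 10 appears only in nomogram display transforms;
* a negative $\hat\beta^{\,\mathrm{ave}}$ (the declared reference is
  not actually minimum-risk) warns and returns the value — the plots,
  which cannot place it, refuse instead;
* $\mathrm{PAF}_a > 1$ is possible for large ORs and is returned
  unclipped, with a warning, so graphics stay honest.

The impact fraction of an intervention moving prevalence from $P$ to
$P'$ is defined as the difference of the two approximate PAFs,
$(P - P')\,\hat\beta^{\,\mathrm{ave}}$ (`impact_fraction_approx()`).
An alternative reading — "the approximate PAF at the new prevalence" —
coincides with this exactly when the intervention halves the
prevalence, which is why the halved-hypertension illustration can be
described both ways; the difference reading is implemented because it
generalises correctly to arbitrary reductions.

## When the approximation breaks: the bias surface

`bias_surface()` evaluates both estimators on a
(control prevalence $p$, odds ratio) grid.  The exact side needs the
case prevalence; it is derived by multiplying the control exposure
odds by the OR,

$$\pi_c = \frac{\mathrm{OR}\cdot p}{1 - p + \mathrm{OR}\cdot p},$$

which is exact for a marginal 2×2 odds ratio and consistent with the
rare-disease conditional≈marginal approximation.  This convention is
isolated in `case_prevalence_from_control()` so it can be swapped if a
different construction is wanted.  At $\mathrm{OR}=1$ both PAFs vanish
and the relative bias $B_r = \mathrm{PAF}_a/\mathrm{PAF}$ is set to 1
by continuity (the absolute bias to 0) so surfaces render without
holes.

Properties the test-suite verifies numerically rather than citing:
$B_r$ underestimates for $p$ below roughly $0.5$ and overestimates
above it; the approximation is most accurate near $p = 0.5$; and the
worst-case relative discrepancy at OR 1.5 over $p \in [0.05, 0.90]$
(step 0.01), computed by `max_relative_bias()`, is

```{r}
max_relative_bias(1.5, c(0.05, 0.90), 0.01)
```

Default grids (prevalence 0.05–0.95 by 0.01, OR 1.05–5 by 0.05) are a
resolution choice, nothing more.

## Graphics

**Fan plot.**  Factor $i$ sits at $(1/\hat P_i,
\hat\beta^{\,\mathrm{ave}}_i)$; the ray from the origin through it has
slope $\hat P_i \hat\beta^{\,\mathrm{ave}}_i = \mathrm{PAF}_a$, and
because the vertical axis is drawn at $1/\hat P = 1$ the same number
is its intercept.  Prevalence decreases left to right; the x-axis is
labelled in prevalence units by default (`xlab_mode = "inverse"`
switches to raw $1/\hat P$), and a right-hand axis maps
$y \mapsto e^y$ to display odds ratios.  Continuous exposures, whose
conventional prevalence is 1, sit on the left boundary.

**Nomogram.**  Taking logs of $\mathrm{PAF}_a = \hat P
\hat\beta^{\,\mathrm{ave}}$ gives
$\log \mathrm{PAF}_a = \log \hat P + \log \hat\beta^{\,\mathrm{ave}}$,
so with three parallel axes at $x = 0, \tfrac12, 1$ and the middle
axis at half scale, each factor's three values are exactly collinear —
the same construction as the likelihood-ratio nomograms of diagnostic
testing.  Axis spacing is not dictated by the mathematics; equal
spacing with a half-scale middle axis is the standard choice and is
fixed here.  Display coordinates use $\log_{10}$ (any base preserves
collinearity; 10 gives readable ticks), with tick sets
prevalence $\{1,2,5,\dots,90\%\}$, OR $\{1.1,1.2,1.5,2,3,5\}$, PAF
$\{1,2,\dots,100\%\}$.

Tilts — lines re-drawn at an alternative prevalence, pivoting on the
left-axis point — are only meaningful when the left axis is the
odds-ratio axis (`ordering = "or-left"`): the pivot must be the one
quantity the tilt does not change.  Tilts under the prevalence-left
ordering are refused.  Interventions (lower prevalence) draw red
dashed, alternative populations (higher prevalence) blue dashed.

Rendering (SVG/PNG via the cairo devices) is byte-deterministic for a
fixed layout, which the tests exploit; layouts also serialise to JSON
for external re-rendering.

## Continuous exposures

The dose-response curve $\hat\beta(j)$ is a natural cubic spline
(default 4 df, user-overridable) inside a plain logistic fit — a
deterministic, fixed-basis stand-in for the nonparametric smooth one
might otherwise use, chosen so that refits (and bootstrap replicates)
are reproducible.  The reference $j_0$ is the argmin of the fitted
curve over a 501-point grid spanning the 1st–99th percentile of the
observed exposure; trimming keeps $j_0$ a *realizable* value away from
the spline's poorly-supported tails, and ties (a flat curve) break to
the smallest value.  The curve is then re-anchored by subtracting
$\hat\beta(j_0)$ — equivalent to re-parameterising the basis, and
simpler.  The density integrals of the continuous-exposure formulas
are evaluated as plug-in means over the observed control/case samples;
this avoids any bandwidth choice and is the natural empirical
estimator.

## Bootstrap

Confidence intervals are stratified nonparametric percentile
bootstrap: cases and controls resampled with replacement separately
(respecting the outcome-dependent design), the full pipeline re-run
per replicate, intervals from the percentiles of the replicate PAFs.
Replicates where the refit fails — non-convergence, separation, or an
exposure level missing from a stratum in the resample — are skipped
and counted; more than 10% failures aborts with an error rather than
returning an interval built on a biased subset.  Given the same seed
the resample stream is identical whatever the requested level, so a
99% interval always contains the 95% one.  The spline basis and the
reference-search grid are held at their full-data configuration across
replicates.

## The synthetic-data generator

`sim_config()`/`simulate_cohort()` generate cohorts from exactly the
logistic model above, with potential outcomes materialised per subject
from a single uniform draw (monotone coupling), so consistency holds
by construction and `true_paf_monte_carlo()` can evaluate the
counterfactual PAF definition directly.  Confounding is induced by one
binary (or normal) confounder shifting both exposure and outcome
log-odds — the minimal structure needed to verify that adjusted fits
remove a bias that unadjusted fits provably retain.
`sample_case_control()` then draws the study: uniform without
replacement within outcome strata, counterfactual columns stripped.
One root seed spawns named substreams (confounder, exposure, outcome,
sampling), so adding a stage never perturbs earlier draws.

Defaults describe the conditions the package is meant for: a common
lifestyle-type risk factor (control prevalence 0.4, within the
0.13–0.84 range of the motivating stroke factors), conditional OR 1.5
(the boundary of the approximation's validity regime), baseline
disease log-odds $\operatorname{qlogis}(0.01)$ (stroke-like rarity),
confounder effects of 0.5 on both log-odds scales, cohort $10^5$.
For continuous exposures the default is a standard-normal exposure
with a linear log-OR curve (slope 0.2) anchored two standard
deviations below the mean — a realizable low-exposure reference.

What the generator does *not* emulate: effect modification (excluded
by assumption), matched designs, survey weights, measurement error,
missingness mechanisms, and the multi-country covariate structure of
real consortium data.  Passing the simulation-based tests therefore
shows the estimators are correct *under their own assumptions*, not
that those assumptions hold in any particular study.

## Validation problem sizes

The test-suite's stochastic checks use sizes chosen to make
Monte-Carlo error small relative to the effects tested while keeping
the default run quick: parameter recovery at 5,000/5,000 cases and
controls over 20 seeds against a truth computed from $2\times10^6$
counterfactual subjects; bootstrap coverage at the 95% level over 200
replicate studies of 1,000/1,000 with 199 resamples each; analytic
prevalence checks at $2\times10^6$.  Deterministic identities (layout
collinearity, fan intercepts, surface-vs-brute-force equality, binary
reduction) are asserted to $10^{-10}$–$10^{-12}$.

## Known limitations

* Everything downstream of the logistic fit inherits the rare-disease
  and no-interaction assumptions; with common outcomes or
  effect-modification the exact estimator is biased, not just the
  approximation.
* The approximation degrades for large ORs and extreme prevalences;
  use `bias_surface()` before trusting $\mathrm{PAF}_a$ numerically,
  and treat fan/nomogram positions as rankings rather than precise
  values there.
* Matched/conditional designs, multiple imputation, survey weights
  and sequential/average attributable fractions are out of scope.
* Ranking artificially discretised versions of continuous risk
  factors against genuinely continuous ones is statistically fragile:
  discretisation without a threshold effect typically disadvantages a
  factor in the comparison.
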