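---
title: "Models and design choices in heatparadox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in heatparadox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(heatparadox)
```

This vignette is the package's account of its statistical machinery: the
two regression models, the quantities derived from them, the synthetic
generators used to validate everything, and the places where the design
was genuinely open and a choice had to be made.

## 1. The heat–mortality model

Daily death counts $Y_t$ in one city stratum are modelled with a
distributed lag non-linear model (DLNM) fitted by quasi-Poisson
regression on warm-season (May–September) days:

$$\log E[Y_t] \;=\; \sum_{l=0}^{3}\sum_{j=1}^{3}\beta_{jl}\,
b_j(T_{t-l}) \;+\; \text{seasonal}(t).$$

* **Exposure basis** $b_1,b_2,b_3$: a natural cubic spline with two
  internal knots at the 50th and 90th percentiles of the analysis-row
  temperatures and boundary knots at their observed range. Natural
  (second-derivative-zero) boundary conditions give linear extrapolation
  beyond the observed range. There is no intercept column in the basis —
  the model intercept lives in the seasonal block, which avoids rank
  deficiency.
* **Lag basis**: one unconstrained stratum per integer lag 0–3 days. With
  only four lags this is the richest choice and imposes no shape on the
  within-window lag distribution; it is also the easiest to reason about
  when assembling cumulative contrasts. Alternative lag bases are a
  deliberate non-goal.
* **Cross-basis column order** is fixed and documented (lag-major within
  exposure: `b1.l0, b1.l1, ..., b3.l3`) because prediction contrast
  vectors must match it bit-exactly.
* **Seasonal control**: intercept + year dummies (reference = first
  year) + a 4-df natural spline of the day of the year + all products of
  the spline columns with the year dummies. The interaction lets each
  year have its own seasonal shape; the main effects are kept alongside
  so the design follows standard factor-expansion semantics and stays
  full rank. A single year of data degenerates to intercept + spline.
* **Quasi-Poisson**: the IRLS point estimates are identical to Poisson
  maximum likelihood; the Pearson dispersion
  $\hat\varphi = \chi^2_P/(n-p)$ scales only the covariance. Convergence
  tolerance is $10^{-9}$ relative deviance change, at most 100
  iterations; rank deficiency is an error naming the collinear columns,
  never a silent drop.

**Lag construction before subsetting.** The lagged temperature matrix is
built on the full contiguous calendar first and only then are outcome
rows restricted to May–September, so the lags of early-May days come from
late April. Subsetting first would silently splice the previous
September into May — a classic DLNM pitfall this package structurally
avoids. Calendar gaps split the series into blocks, each with its own
burn-in masking; masked rows are `NA`, never zero-filled.

### Derived quantities

The **overall cumulative exposure–response curve** at temperature $T$
uses the contrast vector $c(T)$ that repeats the exposure-basis row at
$T$ across all four lag strata. Centered at a reference $T_0$:
$\widehat{\log RR}(T) = (c(T)-c(T_0))^\top\hat\beta_{cb}$ with variance
$(c(T)-c(T_0))^\top\hat\Sigma_{cb}(c(T)-c(T_0))$. The curve is exactly
zero with zero SE at its reference.

The **MMT** is the grid argmin of the curve between the 1st and 99th
temperature percentiles on a 0.1 °C grid, ties broken toward the cooler
temperature. The percentile scale is the warm-season analysis
distribution (the same scale the knots use); full-year scales would shift
the reported percentile but not the temperature.

**RRs at the 90th/99th percentiles** are $\exp$ of the curve at the grid
point nearest each percentile, with Wald 95 % intervals
$\exp(\widehat{\log RR} \pm 1.96\,\widehat{se})$. The interval method is a
choice (the convention in this literature); profile or simulation
intervals are out of scope.

**Stratified analysis** fits the whole population first, extracts the
city-wide MMT, then fits sex and sex-by-age strata with curves centered
at that shared MMT, so every stratum reports RR exactly 1 there and
stratum curves are directly comparable. Exposure knots are likewise
computed once from the whole-population analysis temperatures and shared
(`shared_knots = TRUE`; per-stratum knots are available behind the flag
for sensitivity). A failed stratum is recorded with its error message and
does not abort the city run.

## 2. The survey model

The outcome is the count (0–11) of "yes" answers over eleven heat-related
symptom items; any missing item makes the outcome missing (complete-case,
consistent with a listwise-deletion design; imputation is out of scope).
Predictors are encoded exactly as in the coefficient table: female; age
in raw years (matching the per-year coefficient scale; age groups were
the plausible alternative); married/partnership; lives alone; two
education indicators vs up-to-primary; good / very good financial
situation vs the four lower answer categories (matched against the
questionnaire's verbatim answer strings); uses A/C (almost) always;
self-rated health 0–10; five condition indicators; obesity = BMI ≥ 30
(the WHO convention — the cutoff is a parameter); smokes regularly;
weekly physical activity.

The estimator is weighted least squares with the post-stratification
weights treated as probability weights: they enter the point estimator
$(X^\top WX)^{-1}X^\top Wy$ *and* the HC1 sandwich meat
$\sum_i w_i^2 e_i^2 x_i x_i^\top$ (bread $(X^\top WX)^{-1}$, small-sample
factor $n/(n-p)$), so all reported quantities are invariant to rescaling
the weights. Inference is t with $n-p$ df; the overall test is a robust
Wald F. Because it is ambiguous whether published survey tables of this
kind are weighted or unweighted, both paths run behind the `weighted`
flag (default weighted). VIFs are computed on the final design by
auxiliary regressions; perfect collinearity is reported as `Inf`.

## 3. The paradox rule

The vulnerability-paradox concept is narrative in the field, so the
package's rule is a declared formalisation with explicit, configurable
thresholds: risk is elevated when the RR's 95 % CI lies above 1;
experiences are elevated (resp. reduced) when the coefficient is positive
(resp. non-positive) with $p < 0.1$ — the outermost significance star of
the conventional table — and a coefficient below 0.1 experiences in
magnitude is treated as no effect (a subjective negligibility bound,
documented as such). The verdict is `paradox` exactly for elevated risk
with non-elevated experiences, `aligned` when the sides agree, and
`indeterminate` otherwise — including the reverse mismatch (risk not
elevated, experiences elevated), which is discordant but is not this
paradox, and any factor with a missing side (never a silent paradox).

## 4. What the generators emulate — and what they do not

**Temperature** is an annual cosine plus stationary AR(1) noise. The
city profiles are calibrated so the *warm-season marginal distribution*
matches each city's landmarks: Warsaw ≈ 8.5 °C at P2, 22.7 at P90,
26.5 at P99 (annual mean 8.5, amplitude 12.0, AR 0.7, innovation sd
2.4 °C, 17 years); Madrid ≈ 15.5 at P5, 30.7 at P90, 33.6 at P99
(mean 13.5, amplitude 15.5, AR 0.7, sd 2.0 °C, 10 years). The Madrid
amplitude exceeds the city's true annual cycle — the generator aims at
the warm-season distribution, not at station realism; heat-wave
clustering beyond AR(1) persistence, urban-island structure and
measurement quirks of real station data are deliberately absent. Passing
recovery tests therefore demonstrate estimator correctness under the
stated stochastic model, not robustness to every feature of real series.

**The generating exposure–response curve** is solved inside the same
3-df natural-spline family the model fits (knots from the same
temperatures), so the truth is exactly representable and recovery tests
measure estimator bias with zero approximation error. Three conditions
determine the three coefficients: the log-RR gaps at the 90th and 99th
percentiles relative to the MMT, and — the default third condition —
*stationarity* $f'(\text{MMT}) = 0$, which makes the nominal MMT the
curve's actual argmin and produces an emergent mild cold-side rise
(RR ≈ 1.01 at the warm-season minimum). The alternative `anchor = "cold"`
mode pins the cold-side level (default RR 1.05 at the minimum) instead;
it reproduces a stated cold-side value but the solved cubic then attains
its minimum away from the nominal MMT, so it is unsuitable for
MMT-recovery experiments and is kept as an explicit, documented mode.

**Counts** are negative binomial (variance = mean × 1.3 by default; the
overdispersion of real city series is unknown, so 1.3 is a flagged guess,
and 1 gives pure Poisson) around
$\log\mu_t = \log(\text{baseline}) + 0.1\cos(2\pi(\text{doy}_t-15)/365.25)
+ \sum_l w_l f(T_{t-l})$ with lag weights $w = (0.4, 0.3, 0.2, 0.1)$ — a
front-loaded profile chosen once (the within-window lag distribution of
the real associations is not published) — and a winter-peaked log-scale
seasonal baseline of amplitude 0.1, a low-amplitude stand-in for whatever
seasonal shape the real baseline has. Baselines of 46.6 (Warsaw) and
69.6 (Madrid) deaths/day reproduce the two cities' published May–September
death totals in expectation; the first three days carry no counts
(incomplete lag history), and a missing temperature propagates to missing
counts rather than imputation.

**Survey data** come from a latent Gaussian
$y^* = \alpha + x^\top\beta + \varepsilon$, rounded and clipped to
$[0,11]$ then decomposed into 11 binary items, precisely so that the OLS
estimand equals the generating $\beta$ (a binomial-thinning outcome would
not have that property). The default $\beta$ is the Warsaw coefficient
column, $\alpha = 3$, residual sd 2. The covariate model was chosen for
**estimand fidelity first**: fewer than 2 % of latent outcomes may be
altered by the observation window, which forces a low prevalence of
post-primary education (2 % + 2 %) and a low self-rated-health mean
(Binomial(10, 0.12)) because those coefficients are large and negative.
This is deliberately unrealistic demography; the generator validates the
estimator, it does not impersonate a city's older population. Two
residual-attenuation effects survive even so and are documented rather
than hidden: the education coefficients are biased toward zero (their
subgroups sit near the outcome floor — asserted in the tests as a
direction and bound, and excluded from the unbiasedness family), and the
depression coefficient carries an attenuation of roughly 0.03 (≈ 1.7 %
of its value) from differential upper-tail clipping. Weights are
log-normal (sdlog 0.2) normalised to mean 1 and independent of the
covariates, so the weighted estimator stays unbiased.

## 5. Numerical choices and degenerate inputs

* Quantiles everywhere use linear order-statistic interpolation
  (`type = 7`), stated once and used consistently for knots, percentile
  lookups and MMT bounds.
* Curve grids default to 0.1 °C; the MMT tie-break is toward the cooler
  temperature; grid points beyond the boundary knots are allowed
  (natural linear extrapolation) but flagged.
* IRLS tolerance $10^{-9}$, max 100 iterations, start at
  $\beta = 0$ except intercept $= \log(\bar y + 0.5)$ (glm's default
  initialisation); non-convergence warns, never silently passes.
* The truth-curve calibration solves a 3×3 linear system; a degenerate
  temperature distribution (coincident knots, singular system) is an
  explicit error.
* Constant series, duplicate dates, unknown category labels, negative
  counts, non-positive weights and rank-deficient designs all fail
  loudly with the offending field, line or column named.

## 6. Validation design and problem sizes

The test suite validates every numeric kernel against an independent
oracle (truncated-power natural-spline construction, a Newton score
solver for the GLM, longhand HC1 matrix arithmetic plus
`sandwich::vcovHC` as a second route, brute-force scans for the MMT) and
then runs parameter-recovery studies at the study scale: 25 replicates of
the 17-season Warsaw and 10-season Madrid whole-population designs, a
stratified Madrid design with six sex-by-age strata whose women-85+
stratum carries elevated truth (baseline 10 deaths/day), 100 replicates
for bias/coverage of the log-RR estimator (centered at the true MMT to
isolate estimator bias from MMT-estimation noise), 100 null-surface
replicates at a reduced 5-year scale for coverage of RR = 1, and 50
survey replicates at n = 1050 (300 for the size of the robust t-test).
These sizes keep the full suite under a minute while leaving Monte-Carlo
error well below the tolerances being asserted.

Two statistical caveats in the suite's own design: with 18 survey
coefficients, a per-coefficient 2-SE recovery rule would false-alarm on
about one coefficient per run even for an unbiased estimator, so the
family-wise test uses a 3-SE (Bonferroni-flavoured) bound; and the MMT of
a curve this flat near its minimum (the generating log-RR varies by less
than 0.01 over several degrees on the cold side) is intrinsically weakly
identified — single-replicate MMT estimates spread over several °C, which
is a property of the estimand, not an estimator defect, and is why MMT
recovery is only asserted on the replicate mean.

## 7. Known limitations

* Attributable-fraction computation, multi-city pooling, mortality
  displacement, penalized splines and alternative lag bases are out of
  scope.
* The paradox rule is one faithful formalisation of a narrative concept;
  its thresholds are parameters, not claims.
* The generators' independence assumptions (AR(1) noise, independent
  count noise across strata, covariate-independent weights) are the
  simplest members of their families; conclusions about real data
  require the usual caution.
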