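# heatparadox

Heat kills, and it kills unevenly: mortality risk on hot days rises most for
the oldest adults, yet those same groups often *report* fewer heat-related
symptoms — a mismatch this package calls the **vulnerability paradox**
(elevated objective risk without elevated subjective experience).
`heatparadox` implements both quantitative arms needed to detect it, plus
synthetic-data generators so the whole pipeline is testable without access
to restricted mortality registers.

## What it computes

**Epidemiological arm.** Daily all-cause death counts are modelled against
daily mean temperature with a distributed lag non-linear model (DLNM) fitted
by quasi-Poisson regression over the warm season (May–September):

    log E[Y_t] = cb(T_t, ..., T_{t-3}) + ns(doy_t, 4) x year_t

where the cross-basis `cb` is the tensor product of a natural cubic spline
in temperature (two internal knots at the warm-season 50th and 90th
percentiles, boundary knots at the observed range) with an unconstrained
stratum per lag 0–3, and seasonality/long-term trend are controlled by a
4-df day-of-year spline interacted with a year factor. From the fitted
model the package derives

* the **overall cumulative exposure–response curve** (summed over the lag
  window, with pointwise Wald SEs from the dispersion-scaled covariance),
* the **minimum mortality temperature (MMT)** — the curve's empirical
  minimum searched between the 1st and 99th temperature percentiles, and
* **relative risks at the 90th ("moderate heat") and 99th ("extreme heat")
  percentiles** with 95 % CIs, referenced to the city-wide MMT, for the
  whole population and for sex and sex-by-age strata.

**Survey arm.** A 0–11 count of self-reported heat-related experiences
(eleven symptoms: sweating, headache, dizziness, ... , shortness of breath)
is regressed on demographic, socioeconomic and health predictors by
weighted least squares with heteroskedasticity-robust **HC1** standard
errors and VIF collinearity diagnostics, using age–sex post-stratification
weights.

**Paradox assessor.** For each factor, the epidemiological contrast
(RR with CI) is paired with the survey coefficient; the verdict is
`paradox` exactly when risk is credibly elevated (CI above 1) while
reported experiences are not (significantly negative, or negligible).

**Synthetic generators.** Temperature is an annual sinusoid plus AR(1)
noise, calibrated to each city's warm-season percentile landmarks; the
generating exposure–response curve is solved *inside the fitted spline
family* (so recovery tests carry zero approximation error) with the MMT as
a stationary minimum; counts are negative binomial around the lag-weighted
curve; survey outcomes come from a rounded, clipped Gaussian latent model
with known coefficients.

## Worked example

Simulate a Warsaw-profile city (17 warm seasons, ~46.6 deaths/day, truth
calibrated to RR 1.16 at P90 and 1.39 at P99 with MMT 8.5 °C) and run the
full pipeline:

```r
library(heatparadox)
sim <- simulate_city(warsaw_epi_config(), seed = 1)
res <- run_city(sim$series[, c("date", "deaths", "tmean")], analysis_config())
res$mmt$mmt_temp
#> [1] 7.295648
rr_table(res)
#>   stratum percentile temp    rr ci_low ci_high
#> 1     all         90 23.3 1.164  1.103   1.228
#> 2     all         99 27.2 1.401  1.302   1.509
```

The fitted RRs (1.164 and 1.401) recover the generating values (1.16,
1.39) within sampling error; the estimated MMT sits in the flat cold
region near the generating 8.5 °C (its minimum is weakly identified — see
the vignette); the Pearson dispersion (`res$overall$fit$dispersion`,
here 1.31) recovers the generating overdispersion 1.3.

The survey arm, at the Warsaw sample size with the generating coefficient
vector:

```r
sf <- run_survey_model(simulate_survey(survey_sim_config(), seed = 1))
sf$tidy[sf$tidy$term %in% c("female", "lives_alone", "depression"), ]
#>           term estimate robust_se      t        p stars
#> 2       female  0.69291   0.12727  5.444 6.50e-08   ***
#> 5  lives_alone -0.71054   0.16329 -4.351 1.49e-05   ***
#> 16  depression  1.94984   0.12482 15.621 1.57e-49   ***
```

Estimates recover the generating values (0.677, −0.457, 1.801) within
robust confidence bounds. Pairing a positive mortality contrast with the
negative `lives_alone` coefficient through `assess_paradox()` yields the
`paradox` verdict.

A thin command-line wrapper over the same functions is installed at
`inst/cli/heatparadox-cli.R` with subcommands `simulate-epi`, `fit-epi`,
`simulate-survey`, `fit-survey` and `paradox`, driven by a YAML
configuration; every output directory receives an `effective_config.yaml`
echo sufficient to reproduce the run bit-identically.

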