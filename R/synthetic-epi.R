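#' Temperature generator configuration
#'
#' Daily mean temperature is modelled as an annual sinusoid plus AR(1)
#' noise:
#' `T_t = annual_mean + seasonal_amplitude * cos(2*pi*(doy - peak_day)/365.25) + e_t`,
#' `e_t = ar_coefficient * e_{t-1} + N(0, noise_sd^2)`. This is deliberately
#' minimal: it emulates a city's warm-season temperature distribution
#' (location, spread, day-to-day persistence), not any particular station's
#' record.
#'
#' @param annual_mean degrees C.
#' @param seasonal_amplitude degrees C (half peak-to-trough).
#' @param peak_day_of_year integer 1-366, day of the warmest sinusoid value.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param noise_sd innovation standard deviation, degrees C, `>= 0`.
#' @param n_years number of full calendar years, `>= 1`.
#' @param start_year first calendar year.
#' @return An object of class `temp_config`.
#' @export
temp_config <- function(annual_mean, seasonal_amplitude, peak_day_of_year,
                        ar_coefficient, noise_sd, n_years, start_year) {
  cfg <- list(annual_mean = annual_mean,
              seasonal_amplitude = seasonal_amplitude,
              peak_day_of_year = as.integer(peak_day_of_year),
              ar_coefficient = ar_coefficient,
              noise_sd = noise_sd,
              n_years = as.integer(n_years),
              start_year = as.integer(start_year))
  for (f in names(cfg))
    if (!is.finite(cfg[[f]])) stop("temp_config: non-finite field ", f)
  if (cfg$noise_sd < 0) stop("temp_config: noise_sd must be >= 0")
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop("temp_config: ar_coefficient must be in [0, 1)")
  if (cfg$n_years < 1L) stop("temp_config: n_years must be >= 1")
  if (cfg$peak_day_of_year < 1L || cfg$peak_day_of_year > 366L)
    stop("temp_config: peak_day_of_year must be in 1..366")
  structure(cfg, class = "temp_config")
}

#' Warsaw-profile temperature configuration
#'
#' Defaults calibrated so the simulated May-September distribution matches
#' the Warsaw warm-season landmarks (about 8.5 C at the 2nd percentile,
#' 22.7 C at the 90th, 26.5 C at the 99th) over the 2002-2018 period.
#' @param n_years,start_year overrides for the period.
#' @return a [temp_config()].
#' @export
warsaw_temp_config <- function(n_years = 17L, start_year = 2002L) {
  temp_config(annual_mean = 8.5, seasonal_amplitude = 12.0,
              peak_day_of_year = 200L, ar_coefficient = 0.7,
              noise_sd = 2.4, n_years = n_years, start_year = start_year)
}

#' Madrid-profile temperature configuration
#'
#' Defaults calibrated to the Madrid warm-season landmarks (about 15.5 C at
#' the 5th percentile, 30.7 C at the 90th, 33.6 C at the 99th) over
#' 2010-2019. The amplitude exceeds Madrid's true annual cycle; only the
#' warm-season marginal distribution is being emulated.
#' @param n_years,start_year overrides for the period.
#' @return a [temp_config()].
#' @export
madrid_temp_config <- function(n_years = 10L, start_year = 2010L) {
  temp_config(annual_mean = 13.5, seasonal_amplitude = 15.5,
              peak_day_of_year = 210L, ar_coefficient = 0.7,
              noise_sd = 2.0, n_years = n_years, start_year = start_year)
}

#' Simulate a daily temperature series
#'
#' One record per calendar day for `n_years` full years; reproducible for a
#' fixed seed. With `noise_sd = 0` and `ar_coefficient = 0` the series is
#' exactly the seasonal sinusoid. The AR(1) process is started from its
#' stationary distribution.
#'
#' @param config a [temp_config()].
#' @param seed integer RNG seed.
#' @return data.frame with columns `date`, `tmean`.
#' @export
simulate_temperature <- function(config, seed = 1L) {
  stopifnot(inherits(config, "temp_config"))
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31",
                               config$start_year + config$n_years - 1L)),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  mu <- config$annual_mean + config$seasonal_amplitude *
    cos(2 * pi * (doy - config$peak_day_of_year) / 365.25)
  n <- length(mu)
  if (config$noise_sd > 0) {
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, config$noise_sd /
                           sqrt(1 - config$ar_coefficient^2))
    z <- stats::rnorm(n - 1, 0, config$noise_sd)
    for (t in 2:n) e[t] <- config$ar_coefficient * e[t - 1] + z[t - 1]
  } else e <- numeric(n)
  data.frame(date = dates, tmean = mu + e)
}

#' Calibrate the generating exposure-response curve
#'
#' Builds the 3-column natural spline basis with internal knots at the
#' empirical 50th/90th percentiles of `warm_temps` and boundary knots at its
#' range - the same family the analysis model fits, so the truth is exactly
#' representable (zero approximation error) and recovery tests are
#' unbiased. Solves the 3x3 linear system for the basis coefficients.
#'
#' Two anchoring modes for the third condition:
#' \describe{
#'   \item{`"stationary"` (default)}{`f'(mmt_temp) = 0` alongside
#'     `f(P90) - f(mmt) = log(rr90)` and `f(P99) - f(mmt) = log(rr99)`.
#'     This makes `mmt_temp` a genuine stationary minimum of the generating
#'     curve, so the generative MMT is the curve's argmin, and yields an
#'     emergent mild cold-side rise. Required for meaningful MMT-recovery
#'     experiments.}
#'   \item{`"cold"`}{`f(min) - f(mmt) = log(cold_rr)` instead of the
#'     derivative condition. This pins the cold-side level but the solved
#'     cubic generally attains its minimum away from `mmt_temp` (it dips
#'     below zero between `mmt_temp` and the median), so `mmt_temp` is then
#'     only a normalisation point, not the argmin.}
#' }
#'
#' @param warm_temps warm-season temperatures defining knots and anchors.
#' @param rr90,rr99 target cumulative RR at the 90th/99th percentile
#'   relative to the MMT; must be `> 0`.
#' @param cold_rr target RR at the warm-season minimum (used by the
#'   `"cold"` anchor only); default 1.05.
#' @param mmt_temp generating minimum mortality temperature, inside the
#'   range of `warm_temps`.
#' @param anchor `"stationary"` or `"cold"`, see above.
#' @param lag_weights 4 non-negative weights over lags 0-3 summing to 1.
#' @return An object of class `truth_curve`: `spline_spec`, `theta`,
#'   `mmt_temp`, `lag_weights`, plus the centering `offset`.
#' @export
calibrate_truth <- function(warm_temps, rr90, rr99, cold_rr = 1.05, mmt_temp,
                            anchor = c("stationary", "cold"),
                            lag_weights = c(0.4, 0.3, 0.2, 0.1)) {
  anchor <- match.arg(anchor)
  if (length(warm_temps) == 0L) stop("calibrate_truth: empty warm_temps")
  if (any(c(rr90, rr99, cold_rr) <= 0)) stop("RR targets must be > 0")
  if (mmt_temp < min(warm_temps) || mmt_temp > max(warm_temps))
    stop("mmt_temp must lie within the range of warm_temps")
  if (any(lag_weights < 0) || abs(sum(lag_weights) - 1) > 1e-12)
    stop("lag_weights must be non-negative and sum to 1")
  spec <- spline_spec(percentile_knots(warm_temps, c(50, 90)),
                      range(warm_temps))
  p90 <- percentile_knots(warm_temps, 90)
  p99 <- percentile_knots(warm_temps, 99)
  Bm <- ns_basis(mmt_temp, spec)
  if (anchor == "stationary") {
    h <- 1e-4
    dB <- (ns_basis(mmt_temp + h, spec) - ns_basis(mmt_temp - h, spec)) / (2 * h)
    A <- rbind(ns_basis(p90, spec) - Bm, ns_basis(p99, spec) - Bm, dB)
    b <- c(log(rr90), log(rr99), 0)
  } else {
    A <- rbind(ns_basis(p90, spec) - Bm, ns_basis(p99, spec) - Bm,
               ns_basis(min(warm_temps), spec) - Bm)
    b <- c(log(rr90), log(rr99), log(cold_rr))
  }
  theta <- tryCatch(solve(A, b), error = function(e)
    stop("calibrate_truth: singular calibration system ",
         "(degenerate temperature distribution): ", conditionMessage(e)))
  structure(list(spline_spec = spec, theta = theta, mmt_temp = mmt_temp,
                 lag_weights = lag_weights,
                 offset = drop(Bm %*% theta)),
            class = "truth_curve")
}

#' Evaluate the generating cumulative log relative risk
#'
#' `f(x)` centered so `f(mmt_temp) = 0` exactly.
#' @param truth a [calibrate_truth()] result.
#' @param x temperatures, degrees C.
#' @return numeric vector of cumulative log RR values.
#' @export
truth_logrr <- function(truth, x) {
  stopifnot(inherits(truth, "truth_curve"))
  drop(ns_basis(x, truth$spline_spec) %*% truth$theta) - truth$offset
}

#' Epidemiological simulation configuration
#'
#' @param temp a [temp_config()].
#' @param rr90,rr99,cold_rr,mmt_temp truth-curve calibration targets, see
#'   [calibrate_truth()].
#' @param baseline_daily_deaths expected deaths/day at the MMT with the
#'   seasonal baseline at zero; `> 0`.
#' @param seasonal_baseline_amplitude amplitude of the winter-peaked
#'   log-scale mortality baseline sinusoid (default 0.1).
#' @param overdispersion variance/mean ratio of daily counts, `>= 1`
#'   (1 = Poisson; default 1.3, negative binomial).
#' @param seed integer seed for the generator.
#' @return An object of class `epi_sim_config`.
#' @export
epi_sim_config <- function(temp, rr90, rr99, cold_rr = 1.05, mmt_temp,
                           baseline_daily_deaths,
                           seasonal_baseline_amplitude = 0.1,
                           overdispersion = 1.3, seed = 1L) {
  stopifnot(inherits(temp, "temp_config"))
  if (any(c(rr90, rr99, cold_rr) <= 0)) stop("RR targets must be > 0")
  if (baseline_daily_deaths <= 0) stop("baseline_daily_deaths must be > 0")
  if (overdispersion < 1) stop("overdispersion must be >= 1")
  structure(list(temp = temp, rr90 = rr90, rr99 = rr99, cold_rr = cold_rr,
                 mmt_temp = mmt_temp,
                 baseline_daily_deaths = baseline_daily_deaths,
                 seasonal_baseline_amplitude = seasonal_baseline_amplitude,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "epi_sim_config")
}

#' Warsaw-profile whole-population simulation configuration
#'
#' Truth targets from the Warsaw whole-population cumulative associations
#' (RR 1.16 at P90, 1.39 at P99, MMT 8.5 C); baseline 46.6 deaths/day
#' reproduces the 2002-2018 May-September death total of about 121,000.
#' @param seed integer seed.
#' @return an [epi_sim_config()].
#' @export
warsaw_epi_config <- function(seed = 1L) {
  epi_sim_config(temp = warsaw_temp_config(), rr90 = 1.16, rr99 = 1.39,
                 mmt_temp = 8.5, baseline_daily_deaths = 46.6, seed = seed)
}

#' Madrid-profile whole-population simulation configuration
#'
#' Truth targets from the Madrid whole-population cumulative associations
#' (RR 1.23 at P90, 1.44 at P99, MMT 15.5 C); baseline 69.6 deaths/day
#' reproduces the 2010-2019 May-September death total of about 106,000.
#' @param seed integer seed.
#' @return an [epi_sim_config()].
#' @export
madrid_epi_config <- function(seed = 1L) {
  epi_sim_config(temp = madrid_temp_config(), rr90 = 1.23, rr99 = 1.44,
                 mmt_temp = 15.5, baseline_daily_deaths = 69.6, seed = seed)
}

#' Simulate daily death counts from a known exposure-lag-response surface
#'
#' Log mean deaths on day t:
#' `log(baseline) + s_amp * cos(2*pi*(doy - 15)/365.25) + sum_l w_l f(T_{t-l})`
#' - a winter-peaked low-amplitude seasonal baseline plus the lag-weighted
#' generating curve. Counts are Poisson when `overdispersion = 1`, otherwise
#' negative binomial with matching mean and variance `mean * overdispersion`.
#' The first three days carry no death value (incomplete lag history), and a
#' missing temperature on any required lag day makes that day's count
#' missing rather than imputed.
#'
#' @param series data.frame with `date`, `tmean` (contiguous days).
#' @param truth a [calibrate_truth()] result on the same temperature
#'   support.
#' @param config an [epi_sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return `series` with a `deaths` column filled.
#' @export
simulate_deaths <- function(series, truth, config, seed = config$seed) {
  stopifnot(inherits(truth, "truth_curve"), inherits(config, "epi_sim_config"))
  if (nrow(series) < 4L) stop("series must span at least 4 consecutive days")
  set.seed(seed)
  n <- nrow(series)
  doy <- as.integer(format(series$date, "%j"))
  f <- ifelse(is.na(series$tmean), NA_real_,
              truth_logrr(truth, ifelse(is.na(series$tmean),
                                        truth$mmt_temp, series$tmean)))
  w <- truth$lag_weights
  heat <- rep(NA_real_, n)
  for (t in 4:n) heat[t] <- sum(w * f[t - 0:3])
  lmu <- log(config$baseline_daily_deaths) +
    config$seasonal_baseline_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    heat
  mu <- exp(lmu)
  deaths <- rep(NA_integer_, n)
  ok <- !is.na(mu)
  if (config$overdispersion > 1) {
    deaths[ok] <- stats::rnbinom(sum(ok), mu = mu[ok],
                                 size = mu[ok] / (config$overdispersion - 1))
  } else {
    deaths[ok] <- stats::rpois(sum(ok), mu[ok])
  }
  deaths[1:3] <- NA_integer_
  series$deaths <- deaths
  mu[1:3] <- NA_real_
  attr(series, "mu") <- mu  # expected daily counts, for calibration checks
  series
}

#' Simulate a whole-population city series
#'
#' Convenience wrapper: temperature series, truth curve calibrated on its
#' warm-season (May-September) temperatures, then daily deaths. The death
#' draw uses `seed + 500000` so temperature and counts are independent
#' streams.
#'
#' @param config an [epi_sim_config()].
#' @param seed replicate seed (defaults to `config$seed`).
#' @param anchor truth anchoring mode, see [calibrate_truth()].
#' @return list with `series` (date, tmean, deaths), `truth`, and `config`.
#' @export
simulate_city <- function(config, seed = config$seed, anchor = "stationary") {
  stopifnot(inherits(config, "epi_sim_config"))
  series <- simulate_temperature(config$temp, seed = seed)
  warm <- series$tmean[as.integer(format(series$date, "%m")) %in% 5:9]
  truth <- calibrate_truth(warm, config$rr90, config$rr99, config$cold_rr,
                           config$mmt_temp, anchor = anchor)
  series <- simulate_deaths(series, truth, config, seed = seed + 500000L)
  list(series = series, truth = truth, config = config)
}

#' Simulate a stratified city (sex by age group)
#'
#' One shared temperature series; each stratum gets its own truth curve
#' (anchored at the shared city MMT) and its own baseline, with independent
#' count noise. Strata are defined by a data.frame with columns `sex`,
#' `age_group`, `baseline`, `rr90`, `rr99`.
#'
#' @param config an [epi_sim_config()] (its `baseline_daily_deaths` is
#'   ignored in favour of the per-stratum baselines).
#' @param strata data.frame as described above.
#' @param seed replicate seed.
#' @return list with `series` (long data.frame: date, tmean, deaths, sex,
#'   age_group), `truths` (named list), and `config`.
#' @export
simulate_city_strata <- function(config, strata, seed = config$seed) {
  stopifnot(inherits(config, "epi_sim_config"))
  need <- c("sex", "age_group", "baseline", "rr90", "rr99")
  if (!all(need %in% names(strata)))
    stop("strata must have columns ", paste(need, collapse = ", "))
  temp <- simulate_temperature(config$temp, seed = seed)
  warm <- temp$tmean[as.integer(format(temp$date, "%m")) %in% 5:9]
  out <- vector("list", nrow(strata))
  truths <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    tr <- calibrate_truth(warm, strata$rr90[i], strata$rr99[i],
                          config$cold_rr, config$mmt_temp)
    cfg_i <- config
    cfg_i$baseline_daily_deaths <- strata$baseline[i]
    si <- simulate_deaths(temp, tr, cfg_i, seed = seed + 500000L + i * 1000L)
    si$sex <- strata$sex[i]
    si$age_group <- strata$age_group[i]
    out[[i]] <- si
    truths[[i]] <- tr
  }
  names(truths) <- paste(strata$sex, strata$age_group, sep = ":")
  list(series = do.call(rbind, out), truths = truths, config = config)
}
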