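test_that("temperature equals the sinusoid exactly in the noiseless limit", {
  cfg <- temp_config(10, 8, 200, 0, 0, 1, 2015)
  s <- simulate_temperature(cfg, seed = 1)
  doy <- as.integer(format(s$date, "%j"))
  expect_equal(s$tmean, 10 + 8 * cos(2 * pi * (doy - 200) / 365.25),
               tolerance = 1e-12)
  expect_equal(nrow(s), 365L)
})

test_that("temperature generator honours the seed contract", {
  cfg <- warsaw_temp_config(n_years = 2)
  a <- simulate_temperature(cfg, seed = 7)
  b <- simulate_temperature(cfg, seed = 7)
  c_ <- simulate_temperature(cfg, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$tmean, c_$tmean)))
})

test_that("temp config rejects non-finite and out-of-range fields", {
  expect_error(temp_config(NA, 8, 200, 0.5, 2, 1, 2015), "annual_mean")
  expect_error(temp_config(10, 8, 200, 1.0, 2, 1, 2015), "ar_coefficient")
  expect_error(temp_config(10, 8, 200, 0.5, -1, 1, 2015), "noise_sd")
})

test_that("Warsaw profile hits the warm-season 90th percentile landmark", {
  s <- simulate_temperature(warsaw_temp_config(), seed = 1)
  warm <- s$tmean[as.integer(format(s$date, "%m")) %in% 5:9]
  p90 <- quantile(warm, 0.9, names = FALSE)
  expect_lt(abs(p90 - 22.7), 1.5)
})

test_that("null calibration targets give an identically zero curve", {
  set.seed(31)
  warm <- runif(500, 5, 30)
  tr <- calibrate_truth(warm, 1, 1, 1, mmt_temp = 12)
  expect_equal(unname(tr$theta), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(truth_logrr(tr, seq(5, 30, by = 1)), rep(0, 26),
               tolerance = 1e-12)
})

test_that("calibrated curve reproduces its RR targets and centering", {
  s <- simulate_temperature(warsaw_temp_config(), seed = 1)
  warm <- s$tmean[as.integer(format(s$date, "%m")) %in% 5:9]
  tr <- calibrate_truth(warm, rr90 = 1.16, rr99 = 1.39, mmt_temp = 8.5)
  p90 <- percentile_knots(warm, 90)
  p99 <- percentile_knots(warm, 99)
  expect_equal(truth_logrr(tr, p90), log(1.16), tolerance = 1e-10)
  expect_equal(truth_logrr(tr, p99), log(1.39), tolerance = 1e-10)
  expect_equal(truth_logrr(tr, 8.5), 0, tolerance = 1e-12)
  # the MMT is the argmin of the generating curve (stationary anchor)
  g <- seq(percentile_knots(warm, 1), percentile_knots(warm, 99), by = 0.01)
  expect_lt(abs(g[which.min(truth_logrr(tr, g))] - 8.5), 0.05)
})

test_that("calibrated curve agrees with a truncated-power re-solution", {
  # independent oracle: solve the same constraint equations in the
  # truncated-power natural-spline basis and compare curve values
  set.seed(32)
  warm <- runif(800, 3, 30)
  tr <- calibrate_truth(warm, 1.2, 1.5, cold_rr = 1.05, mmt_temp = 10,
                        anchor = "cold")
  knots <- sort(c(range(warm), percentile_knots(warm, c(50, 90))))
  pts <- c(percentile_knots(warm, 90), percentile_knots(warm, 99), min(warm))
  A <- tp_natural_basis(pts, knots) - rep(1, 3) %o%
    drop(tp_natural_basis(10, knots))
  # drop the intercept column (differences annihilate it) and solve
  cf <- solve(A[, -1], log(c(1.2, 1.5, 1.05)))
  x_new <- seq(4, 29, by = 0.5)
  oracle <- drop((tp_natural_basis(x_new, knots) -
                    rep(1, length(x_new)) %o%
                    drop(tp_natural_basis(10, knots)))[, -1] %*% cf)
  expect_equal(truth_logrr(tr, x_new), oracle, tolerance = 1e-8)
})

test_that("cold-anchored calibration pins the cold-side level", {
  set.seed(33)
  warm <- runif(500, 3, 30)
  tr <- calibrate_truth(warm, 1.2, 1.5, cold_rr = 1.08, mmt_temp = 10,
                        anchor = "cold")
  expect_equal(truth_logrr(tr, min(warm)), log(1.08), tolerance = 1e-10)
})

test_that("degenerate temperature distributions fail calibration loudly", {
  expect_error(calibrate_truth(rep(c(9.9, 10.1), 50), 1.2, 1.5,
                               mmt_temp = 10),
               "singular|strictly inside")
})

test_that("constant-rate death generator matches its baseline", {
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 10),
                        rr90 = 1, rr99 = 1, cold_rr = 1, mmt_temp = 8.5,
                        baseline_daily_deaths = 50,
                        seasonal_baseline_amplitude = 0,
                        overdispersion = 1, seed = 5)
  sim <- simulate_city(cfg, seed = 5)
  d <- sim$series$deaths
  m <- mean(d, na.rm = TRUE)
  se <- sd(d, na.rm = TRUE) / sqrt(sum(!is.na(d)))
  expect_lt(abs(m - 50), 3 * se)
})

test_that("expected counts follow the generative formula exactly", {
  # single day with known temperature history and weights 0.4/0.3/0.2/0.1
  s <- simulate_temperature(warsaw_temp_config(n_years = 1), seed = 3)
  warm <- s$tmean[as.integer(format(s$date, "%m")) %in% 5:9]
  tr <- calibrate_truth(warm, 1.3, 1.6, mmt_temp = 10)
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 1),
                        rr90 = 1.3, rr99 = 1.6, mmt_temp = 10,
                        baseline_daily_deaths = 40, seed = 3)
  sim <- simulate_deaths(s, tr, cfg)
  mu <- attr(sim, "mu")
  t0 <- 200
  doy <- as.integer(format(s$date[t0], "%j"))
  by_hand <- 40 * exp(0.1 * cos(2 * pi * (doy - 15) / 365.25) +
    sum(c(0.4, 0.3, 0.2, 0.1) * truth_logrr(tr, s$tmean[t0 - 0:3])))
  expect_equal(mu[t0], by_hand, tolerance = 1e-12)
  expect_true(all(is.na(sim$deaths[1:3])))
})

test_that("missing lag temperatures yield missing counts, not imputation", {
  s <- simulate_temperature(warsaw_temp_config(n_years = 1), seed = 4)
  s$tmean[100] <- NA
  warm_cfg <- warsaw_epi_config()
  tr <- calibrate_truth(seq(2, 28, by = 0.1), 1.2, 1.4, mmt_temp = 9)
  sim <- simulate_deaths(s, tr, warm_cfg, seed = 9)
  expect_true(all(is.na(sim$deaths[100:103])))
  expect_false(is.na(sim$deaths[104]))
})

test_that("Warsaw defaults reproduce the seasonal death total in expectation", {
  sim <- simulate_city(warsaw_epi_config(), seed = 1)
  mu <- attr(sim$series, "mu")
  warm <- as.integer(format(sim$series$date, "%m")) %in% 5:9
  expected_total <- sum(mu[warm], na.rm = TRUE)
  expect_lt(abs(expected_total - 121240) / 121240, 0.03)
  realised <- sum(sim$series$deaths[warm], na.rm = TRUE)
  expect_lt(abs(realised - expected_total) / expected_total, 0.02)
})

test_that("simulated strata carry their own baselines and truth curves", {
  strata <- data.frame(sex = c("female", "male"),
                       age_group = c("85+", "85+"),
                       baseline = c(10, 6), rr90 = c(1.42, 1.30),
                       rr99 = c(1.76, 1.39))
  sim <- simulate_city_strata(madrid_epi_config(), strata, seed = 2)
  expect_setequal(unique(sim$series$sex), c("female", "male"))
  f <- sim$series[sim$series$sex == "female", ]
  m <- sim$series[sim$series$sex == "male", ]
  expect_gt(mean(f$deaths, na.rm = TRUE), mean(m$deaths, na.rm = TRUE))
  one <- sim$series[sim$series$sex == "female", ]  # shared temperature series
  p99 <- percentile_knots(
    one$tmean[as.integer(format(one$date, "%m")) %in% 5:9], 99)
  expect_equal(exp(truth_logrr(sim$truths[["female:85+"]], p99)), 1.76,
               tolerance = 1e-8)
})
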