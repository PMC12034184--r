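# small fitted DLNM fixture shared across blocks: 2 warm seasons of
# moderate-signal data, enough for curve mechanics without long runtimes
local_fit <- local({
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 3),
                        rr90 = 1.3, rr99 = 1.6, mmt_temp = 9,
                        baseline_daily_deaths = 60, seed = 41)
  sim <- simulate_city(cfg, seed = 41)
  prep <- prepare_series(sim$series, analysis_config())
  seas <- build_seasonal_design(prep$data$date, 4)
  X <- cbind(prep$X_cb, seas)
  fit <- fit_quasipoisson(prep$data$deaths, X)
  list(fit = fit, prep = prep, truth = sim$truth)
})

test_that("a null coefficient vector gives RR identically 1", {
  f <- local_fit$fit
  f0 <- f
  f0$beta[1:12] <- 0
  curve <- cumulative_curve(f0, local_fit$prep$cb, reference = 15,
                            temps = local_fit$prep$temps)
  expect_equal(curve$log_rr, rep(0, length(curve$temp_grid)),
               tolerance = 1e-12)
})

test_that("curve matches manual contrast assembly on a small grid", {
  f <- local_fit$fit
  cb <- local_fit$prep$cb
  grid <- c(6, 10, 15, 20, 24)
  ref <- 12
  curve <- cumulative_curve(f, cb, grid, reference = ref,
                            temps = local_fit$prep$temps)
  # oracle: sum the fitted exposure function over the 4 lag strata by
  # explicit arithmetic, one temperature at a time
  sp <- cb$spline_spec
  fhat <- function(x) {
    b <- ns_basis(x, sp)
    tot <- 0
    for (j in 1:3) for (l in 0:3)
      tot <- tot + b[1, j] * f$beta[(j - 1) * 4 + l + 1]
    tot
  }
  manual <- vapply(grid, fhat, numeric(1)) - fhat(ref)
  expect_equal(curve$log_rr, manual, tolerance = 1e-10)
  # variance oracle at one point
  cvec <- drop(cumulative_contrast(cb, grid[2]) - cumulative_contrast(cb, ref))
  v <- drop(t(cvec) %*% f$cov[1:12, 1:12] %*% cvec)
  expect_equal(curve$se[2], sqrt(v), tolerance = 1e-10)
})

test_that("the curve is exactly centered at its reference", {
  curve <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                            reference = 15, temps = local_fit$prep$temps)
  i <- which.min(abs(curve$temp_grid - 15))
  # reference on the grid: log RR 0, se 0, RR 1 with degenerate CI
  curve2 <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                             temp_grid = sort(c(15, curve$temp_grid)),
                             reference = 15, temps = local_fit$prep$temps)
  j <- which(curve2$temp_grid == 15)
  expect_equal(curve2$log_rr[j], 0)
  expect_equal(curve2$se[j], 0)
  rr <- rr_at(curve2, 100 * mean(local_fit$prep$temps <= 15))
  expect_equal(rr$rr, 1, tolerance = 1e-6)
})

test_that("re-centering a centered curve at the same reference is idempotent", {
  c1 <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                         reference = 14, temps = local_fit$prep$temps)
  c2 <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                         reference = 14, temps = local_fit$prep$temps)
  expect_identical(c1$log_rr, c2$log_rr)
  expect_identical(c1$se, c2$se)
})

test_that("find_mmt scans correctly on convex, monotone and random curves", {
  mk_curve <- function(grid, vals, temps) {
    structure(list(temp_grid = grid, log_rr = vals,
                   se = rep(0.1, length(grid)), reference_temp = grid[1],
                   percentile = 100 * stats::ecdf(temps)(grid),
                   extrapolated = rep(FALSE, length(grid)), temps = temps),
              class = "exposure_response_curve")
  }
  temps <- seq(0, 30, length.out = 2000)
  grid <- seq(0.5, 29.5, by = 0.1)
  # strictly convex with analytic minimum at a grid point
  conv <- mk_curve(grid, (grid - 12.3)^2, temps)
  expect_equal(find_mmt(conv)$mmt_temp, 12.3, tolerance = 1e-9)
  # monotone decreasing: minimum at the upper percentile bound
  dec <- mk_curve(grid, -grid, temps)
  ub <- quantile(temps, 0.99, names = FALSE)
  got <- find_mmt(dec)$mmt_temp
  expect_equal(got, max(grid[grid <= ub]))  # last grid point inside bound
  # random curve on 500 points vs a brute-force scan
  set.seed(42)
  g500 <- seq(1, 29, length.out = 500)
  vals <- rnorm(500)
  rc <- mk_curve(g500, vals, temps)
  lo <- quantile(temps, 0.01, names = FALSE)
  inb <- g500 >= lo & g500 <= ub
  expect_equal(find_mmt(rc)$mmt_temp, g500[inb][which.min(vals[inb])])
  # ties break toward the cooler temperature
  tie <- mk_curve(grid, rep(0, length(grid)), temps)
  expect_equal(find_mmt(tie)$mmt_temp, grid[grid >= lo][1])
  expect_error(find_mmt(conv, bounds = c(0, 99)), "bounds")
})

test_that("rr_at applies the Wald formula on the log scale", {
  curve <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                            reference = 14, temps = local_fit$prep$temps)
  rr <- rr_at(curve, c(90, 99))
  for (k in 1:2) {
    tq <- quantile(local_fit$prep$temps, rr$percentile[k] / 100,
                   names = FALSE)
    i <- which.min(abs(curve$temp_grid - tq))
    expect_equal(rr$rr[k], exp(curve$log_rr[i]), tolerance = 1e-12)
    expect_equal(rr$ci_low[k], exp(curve$log_rr[i] - 1.96 * curve$se[i]),
                 tolerance = 1e-12)
    expect_equal(rr$ci_high[k], exp(curve$log_rr[i] + 1.96 * curve$se[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(rr$ci_low <= rr$rr & rr$rr <= rr$ci_high))
  expect_error(rr_at(curve, 101), "percentiles")
})

test_that("log-RR estimates are unbiased with near-nominal coverage", {
  # 100 replicates of the default Warsaw design, curves centered at the
  # true generating MMT so the measurement isolates estimator bias
  n_rep <- 100
  b90 <- b99 <- numeric(n_rep)
  c90 <- c99 <- logical(n_rep)
  cfg <- warsaw_epi_config()
  for (r in seq_len(n_rep)) {
    sim <- simulate_city(cfg, seed = r)
    prep <- prepare_series(sim$series, analysis_config())
    seas <- build_seasonal_design(prep$data$date, 4)
    fit <- fit_quasipoisson(prep$data$deaths, cbind(prep$X_cb, seas))
    curve <- cumulative_curve(fit, prep$cb, reference = 8.5,
                              temps = prep$temps)
    rr <- rr_at(curve, c(90, 99))
    b90[r] <- log(rr$rr[1]) - log(1.16)
    b99[r] <- log(rr$rr[2]) - log(1.39)
    c90[r] <- rr$ci_low[1] <= 1.16 && 1.16 <= rr$ci_high[1]
    c99[r] <- rr$ci_low[2] <= 1.39 && 1.39 <= rr$ci_high[2]
  }
  expect_lt(abs(mean(b90)), 2 * sd(b90) / sqrt(n_rep))
  expect_lt(abs(mean(b99)), 2 * sd(b99) / sqrt(n_rep))
  expect_gte(mean(c90), 0.90); expect_lte(mean(c90), 0.98)
  expect_gte(mean(c99), 0.90); expect_lte(mean(c99), 0.98)
})

test_that("CI bounds are order-preserving images of the log-scale bounds", {
  curve <- cumulative_curve(local_fit$fit, local_fit$prep$cb,
                            reference = 14, temps = local_fit$prep$temps)
  nz <- curve$se > 0
  expect_true(all(exp(curve$log_rr - 1.96 * curve$se)[nz] <
                  exp(curve$log_rr + 1.96 * curve$se)[nz]))
})
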