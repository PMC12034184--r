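test_that("May outcome rows draw their lags from April, never the previous season", {
  # 10-day toy calendar spanning the April/May boundary
  s <- toy_series(tmean = c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19),
                  start = as.Date("2015-04-27"))
  prep <- prepare_series(s, analysis_config())
  expect_equal(format(prep$data$date[1], "%m-%d"), "05-01")
  # May 1 is row 5 of the raw series: lags are Apr 30..28
  i <- which(prep$keep)[1]
  expect_equal(unname(prep$cb$x[i - 0:3]), c(14, 13, 12, 11))
  expect_true(prep$cb$valid_row_mask[i])
})

test_that("a series starting May 1 masks the burn-in days", {
  s <- toy_series(tmean = seq(10, 19.5, by = 0.5),
                  start = as.Date("2015-05-01"))
  prep <- prepare_series(s, analysis_config())
  expect_equal(format(prep$data$date[1], "%m-%d"), "05-04")
})

test_that("retained analysis rows span the warm months only", {
  sim <- simulate_city(epi_sim_config(temp = warsaw_temp_config(n_years = 2),
                                      rr90 = 1.2, rr99 = 1.4, mmt_temp = 9,
                                      baseline_daily_deaths = 30, seed = 51),
                       seed = 51)
  prep <- prepare_series(sim$series, analysis_config())
  months <- as.integer(format(prep$data$date, "%m"))
  expect_setequal(unique(months), 5:9)
})

test_that("calendar gaps split the series into blocks with own burn-in", {
  set.seed(56)
  s <- toy_series(tmean = runif(40, 10, 25), start = as.Date("2015-05-01"))
  s2 <- toy_series(tmean = runif(40, 12, 27), start = as.Date("2015-07-01"))
  gap <- rbind(s, s2)
  prep <- prepare_series(gap, analysis_config())
  # first 3 rows of each block masked
  expect_false(as.Date("2015-07-01") %in% prep$data$date)
  expect_true(as.Date("2015-07-04") %in% prep$data$date)
})

test_that("seasonal design follows the factor-expansion counting rule", {
  d1 <- seq(as.Date("2015-05-01"), as.Date("2015-09-30"), by = "day")
  X1 <- build_seasonal_design(d1, 4)
  expect_equal(ncol(X1), 5L)  # intercept + 4 spline columns
  d2 <- c(d1, d1 + 365)
  X2 <- build_seasonal_design(d2, 4)
  expect_equal(ncol(X2), 10L)  # 1 + 1 + 4 + 4
  expect_equal(qr(X2)$rank, 10L)
  d3 <- c(d1, d1 + 365, d1 + 730)
  expect_equal(ncol(build_seasonal_design(d3, 4)), 15L)
})

test_that("a year with too few days fails naming the year", {
  d <- c(seq(as.Date("2015-05-01"), as.Date("2015-09-30"), by = "day"),
         as.Date("2016-05-01") + 0:2)
  expect_error(build_seasonal_design(d, 4), "2016")
})

test_that("every stratum reports RR exactly 1 at the city MMT", {
  strata <- data.frame(sex = c("female", "male"),
                       age_group = c("all", "all"),
                       baseline = c(25, 22), rr90 = c(1.2, 1.2),
                       rr99 = c(1.45, 1.45))
  sim <- simulate_city_strata(
    epi_sim_config(temp = warsaw_temp_config(n_years = 4), rr90 = 1.2,
                   rr99 = 1.45, mmt_temp = 9, baseline_daily_deaths = 47,
                   seed = 52), strata, seed = 52)
  res <- run_city(sim$series, analysis_config())
  mmt <- res$mmt$mmt_temp
  for (s in res$strata) {
    expect_s3_class(s, "stratum_result")
    i <- which.min(abs(s$curve$temp_grid - mmt))
    expect_equal(s$curve$log_rr[i], 0, tolerance = 1e-10)
  }
})

test_that("the fitted pipeline is byte-identical across reruns", {
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 3), rr90 = 1.2,
                        rr99 = 1.4, mmt_temp = 9, baseline_daily_deaths = 40,
                        seed = 53)
  sim <- simulate_city(cfg, seed = 53)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_city_results(run_city(sim$series, analysis_config()), d1)
  write_city_results(run_city(sim$series, analysis_config()), d2)
  for (f in c("rr_table.csv", "curves.csv", "mmt.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("pooling two identical strata matches the single-stratum curve", {
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 6), rr90 = 1.25,
                        rr99 = 1.5, mmt_temp = 9, baseline_daily_deaths = 40,
                        seed = 54)
  strata <- data.frame(sex = c("female", "male"),
                       age_group = c("all", "all"),
                       baseline = c(40, 40), rr90 = c(1.25, 1.25),
                       rr99 = c(1.5, 1.5))
  sim <- simulate_city_strata(cfg, strata, seed = 54)
  res <- run_city(sim$series, analysis_config())
  rr <- rr_table(res)
  pooled <- rr[rr$stratum == "all" & rr$percentile == 99, "rr"]
  fem <- rr[rr$stratum == "female:all" & rr$percentile == 99, "rr"]
  # identical generating processes: curves agree within Monte-Carlo error
  expect_lt(abs(log(pooled) - log(fem)), 0.15)
})

test_that("a failed stratum is recorded without aborting the city run", {
  cfg <- epi_sim_config(temp = warsaw_temp_config(n_years = 3), rr90 = 1.2,
                        rr99 = 1.4, mmt_temp = 9, baseline_daily_deaths = 40,
                        seed = 55)
  strata <- data.frame(sex = c("female", "male"),
                       age_group = c("all", "all"),
                       baseline = c(40, 35), rr90 = c(1.2, 1.2),
                       rr99 = c(1.4, 1.4))
  sim <- simulate_city_strata(cfg, strata, seed = 55)
  # sabotage one stratum: keep only 10 days of the male series, far too few
  # rows to support the design
  male_rows <- which(sim$series$sex == "male")
  sim$series <- sim$series[-male_rows[-(121:130)], ]
  res <- run_city(sim$series, analysis_config())
  expect_s3_class(res$overall, "stratum_result")
  expect_s3_class(res$strata[["female:all"]], "stratum_result")
  expect_type(res$strata[["male:all"]], "character")
})
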