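#' Analysis configuration for the city-level pipeline
#'
#' All the analysis choices in one auditable object: the warm-season window,
#' the exposure knot percentiles, the lag window, the seasonal-control
#' degrees of freedom, the MMT search bounds and the reporting percentiles.
#' The configuration is carried verbatim into result objects so a run can be
#' reproduced bit-identically.
#'
#' @param warm_months months whose days enter the outcome rows
#'   (default May-September).
#' @param knot_percentiles internal exposure knot percentiles (default 50, 90).
#' @param max_lag lag window in days (default 3).
#' @param seasonal_df degrees of freedom of the day-of-year spline
#'   (default 4).
#' @param mmt_bounds MMT search percentile bounds (default 1, 99).
#' @param rr_percentiles reporting percentiles (default 90, 99: moderate
#'   and extreme heat).
#' @param shared_knots if `TRUE` (default) exposure knots are computed once
#'   from the whole-population analysis temperatures and shared across
#'   strata so stratum curves are comparable.
#' @param grid_step curve grid resolution in degrees C (default 0.1).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(warm_months = 5:9, knot_percentiles = c(50, 90),
                            max_lag = 3L, seasonal_df = 4L,
                            mmt_bounds = c(1, 99), rr_percentiles = c(90, 99),
                            shared_knots = TRUE, grid_step = 0.1) {
  structure(list(warm_months = as.integer(warm_months),
                 knot_percentiles = knot_percentiles,
                 max_lag = as.integer(max_lag),
                 seasonal_df = as.integer(seasonal_df),
                 mmt_bounds = mmt_bounds, rr_percentiles = rr_percentiles,
                 shared_knots = isTRUE(shared_knots), grid_step = grid_step),
            class = "analysis_config")
}

# contiguous-run ids for a sorted Date vector
.date_blocks <- function(dates) {
  if (is.unsorted(dates)) stop("dates must be sorted")
  c(0L, cumsum(diff(as.integer(dates)) != 1L)) + 1L
}

#' Prepare a daily series for DLNM fitting
#'
#' Builds the lagged temperature matrix on the full contiguous series FIRST
#' and only then restricts the outcome rows to the warm months, so lagged
#' temperatures for early-May days come from late April - never from the
#' previous season. Calendar gaps split the series into blocks, each with
#' its own burn-in masking. Exposure knots default to percentiles of the
#' retained analysis-row temperatures; pass `spec` to share knots across
#' strata.
#'
#' @param raw data.frame with `date`, `deaths`, `tmean` for one stratum.
#' @param config an [analysis_config()].
#' @param spec optional [spline_spec()] overriding the knot computation.
#' @return list: `data` (analysis rows), `X_cb` (cross-basis block on the
#'   analysis rows), `cb` (full cross-basis), `spec`, `temps`
#'   (analysis-row temperatures).
#' @export
prepare_series <- function(raw, config = analysis_config(), spec = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  raw <- raw[order(raw$date), , drop = FALSE]
  if (anyDuplicated(raw$date)) stop("prepare_series: duplicate dates")
  block <- .date_blocks(raw$date)
  lm_ <- lag_matrix(raw$tmean, config$max_lag, block = block)
  month <- as.integer(format(raw$date, "%m"))
  complete_lags <- lm_$valid & rowSums(is.na(lm_$matrix)) == 0L
  keep <- month %in% config$warm_months & complete_lags & !is.na(raw$deaths)
  if (!any(keep)) stop("prepare_series: no usable analysis rows")
  temps <- raw$tmean[keep]
  if (is.null(spec))
    spec <- spline_spec(percentile_knots(temps, config$knot_percentiles),
                        range(temps))
  cb <- cross_basis(raw$tmean, spec, lag_spec(config$max_lag), block = block)
  list(data = raw[keep, , drop = FALSE],
       X_cb = cb$matrix[keep, , drop = FALSE],
       cb = cb, spec = spec, temps = temps, keep = keep)
}

#' Seasonal and long-term trend design
#'
#' Columns: intercept, year main-effect dummies (reference = first year), a
#' natural spline of the day of the year with `seasonal_df` degrees of
#' freedom, and all pairwise products of the spline columns with each year
#' dummy - the interaction between the within-year seasonal shape and the
#' year factor, letting the seasonal curve differ by year. A single year of
#' data degenerates to intercept + spline.
#'
#' @param dates Date vector of the analysis rows.
#' @param seasonal_df spline degrees of freedom (default 4).
#' @return numeric design matrix, full rank on the analysis rows.
#' @export
build_seasonal_design <- function(dates, seasonal_df = 4L) {
  doy <- as.integer(format(dates, "%j"))
  year <- factor(as.integer(format(dates, "%Y")))
  for (lev in levels(year))
    if (sum(year == lev) <= seasonal_df)
      stop("build_seasonal_design: year ", lev,
           " has too few days to support the seasonal spline")
  S <- splines::ns(doy, df = seasonal_df)
  colnames(S) <- paste0("doy", seq_len(ncol(S)))
  if (nlevels(year) == 1L) {
    out <- cbind(`(Intercept)` = 1, S)
  } else {
    out <- stats::model.matrix(~ year * S)
  }
  out
}

#' Fit one stratum and extract its heat-association quantities
#'
#' Design = [cross-basis | seasonal design]; quasi-Poisson fit; overall
#' cumulative curve on a `grid_step` grid; MMT from the curve (unless a
#' city-wide `reference_mmt` is supplied, the recommended usage for strata);
#' RRs with 95 percent CIs at the configured percentiles.
#'
#' @param raw one stratum's data.frame (`date`, `deaths`, `tmean`).
#' @param config an [analysis_config()].
#' @param spec optional shared [spline_spec()].
#' @param reference_mmt optional centering temperature (degrees C); when
#'   `NULL` the stratum's own MMT is used.
#' @param label stratum label carried into outputs.
#' @return list of class `stratum_result`: `curve`, `rr`, `mmt`, `fit`,
#'   `spec`, `label`.
#' @export
run_stratum <- function(raw, config = analysis_config(), spec = NULL,
                        reference_mmt = NULL, label = "all") {
  prep <- prepare_series(raw, config, spec = spec)
  seas <- build_seasonal_design(prep$data$date, config$seasonal_df)
  X <- cbind(prep$X_cb, seas)
  fit <- fit_quasipoisson(prep$data$deaths, X)
  grid <- seq(min(prep$temps), max(prep$temps), by = config$grid_step)
  ref0 <- if (is.null(reference_mmt)) stats::median(prep$temps) else reference_mmt
  curve0 <- cumulative_curve(fit, prep$cb, grid, reference = ref0,
                             temps = prep$temps)
  mmt <- find_mmt(curve0, bounds = config$mmt_bounds)
  ref <- if (is.null(reference_mmt)) mmt$mmt_temp else reference_mmt
  curve <- cumulative_curve(fit, prep$cb, grid, reference = ref,
                            temps = prep$temps)
  rr <- rr_at(curve, config$rr_percentiles, stratum = label)
  structure(list(curve = curve, rr = rr, mmt = mmt, fit = fit,
                 spec = prep$spec, label = label),
            class = "stratum_result")
}

# aggregate death counts over strata sharing the same dates/temperatures
.aggregate_series <- function(series, by_sex = NULL) {
  rows <- series
  if (!is.null(by_sex)) rows <- rows[rows$sex == by_sex, , drop = FALSE]
  agg <- stats::aggregate(deaths ~ date, data = rows, FUN = sum,
                          na.action = stats::na.pass)
  tm <- rows[!duplicated(rows$date), c("date", "tmean")]
  out <- merge(agg, tm, by = "date")
  out[order(out$date), ]
}

#' City-level stratified analysis
#'
#' Fits the whole-population model first, extracts the city-wide MMT, then
#' fits each sex stratum and each sex-by-age stratum with curves centered
#' at that MMT (so every stratum reports RR exactly 1 at the city MMT).
#' Exposure knots are computed from the whole-population analysis
#' temperatures and shared across strata when `config$shared_knots` is
#' `TRUE`. A failed stratum is recorded with its error message and does not
#' abort the city run.
#'
#' @param series long data.frame: `date`, `deaths`, `tmean`, plus optional
#'   `sex` and `age_group` columns for stratified input.
#' @param config an [analysis_config()].
#' @return An object of class `city_results`: `overall` (stratum_result),
#'   `mmt` (city-wide), `strata` (named list of stratum_result or error
#'   strings), `config`.
#' @export
run_city <- function(series, config = analysis_config()) {
  stratified <- all(c("sex", "age_group") %in% names(series))
  overall_series <- if (stratified) .aggregate_series(series)
                    else series[, c("date", "deaths", "tmean")]
  overall <- run_stratum(overall_series, config, label = "all")
  mmt <- overall$mmt
  # re-center the overall curve at its own MMT is already done inside
  strata <- list()
  if (stratified) {
    spec <- if (config$shared_knots) overall$spec else NULL
    combos <- unique(series[, c("sex", "age_group")])
    for (sx in unique(series$sex)) {
      lab <- paste0(sx, ":all")
      strata[[lab]] <- tryCatch(
        run_stratum(.aggregate_series(series, by_sex = sx), config,
                    spec = spec, reference_mmt = mmt$mmt_temp, label = lab),
        error = function(e) conditionMessage(e))
    }
    for (i in seq_len(nrow(combos))) {
      sx <- combos$sex[i]; ag <- combos$age_group[i]
      lab <- paste0(sx, ":", ag)
      sub <- series[series$sex == sx & series$age_group == ag,
                    c("date", "deaths", "tmean")]
      strata[[lab]] <- tryCatch(
        run_stratum(sub, config, spec = spec,
                    reference_mmt = mmt$mmt_temp, label = lab),
        error = function(e) conditionMessage(e))
    }
  }
  structure(list(overall = overall, mmt = mmt, strata = strata,
                 config = config),
            class = "city_results")
}

#' Collect the RR table from a city run
#'
#' @param results a [run_city()] result.
#' @return data.frame `stratum`, `percentile`, `temp`, `rr`, `ci_low`,
#'   `ci_high` over the overall population and every successful stratum.
#' @export
rr_table <- function(results) {
  stopifnot(inherits(results, "city_results"))
  parts <- list(results$overall$rr)
  for (s in results$strata)
    if (inherits(s, "stratum_result")) parts <- c(parts, list(s$rr))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
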