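#' Overall cumulative exposure-response curve
#'
#' Turns a fitted DLNM into the predicted overall cumulative association:
#' for each grid temperature T the contrast vector c(T) (exposure-basis row
#' at T repeated over every lag stratum) is assembled in cross-basis column
#' order, and the centered cumulative log relative risk is
#' `(c(T) - c(ref))' beta_cb` with pointwise variance
#' `(c(T) - c(ref))' Sigma_cb (c(T) - c(ref))` from the dispersion-scaled
#' covariance sub-block. The curve is exactly 0 with zero SE at the
#' reference temperature. Grid points beyond the boundary knots are allowed
#' (the natural spline extrapolates linearly) but flagged.
#'
#' @param fit a `glm_fit` whose design's leading columns are `cb$matrix`
#'   columns in cross-basis order.
#' @param cb the [cross_basis()] used in the fit.
#' @param temp_grid numeric grid of temperatures (strictly increasing). If
#'   `NULL`, a 0.1 degree C grid spanning `temps` is used.
#' @param reference reference temperature (degrees C), typically the MMT.
#' @param temps analysis-row temperatures defining the percentile scale;
#'   defaults to the valid rows of the cross-basis series.
#' @return An object of class `exposure_response_curve` with `temp_grid`,
#'   `log_rr`, `se`, `reference_temp`, `percentile` (grid-to-percentile
#'   lookup), `extrapolated` flags, and the `temps` percentile scale.
#' @export
cumulative_curve <- function(fit, cb, temp_grid = NULL, reference,
                             temps = cb$x[cb$valid_row_mask]) {
  stopifnot(inherits(fit, "glm_fit"), inherits(cb, "cross_basis"))
  ncb <- ncol(cb$matrix)
  if (fit$n_params < ncb)
    stop("fit has fewer parameters than the cross-basis has columns")
  if (is.null(temp_grid))
    temp_grid <- seq(min(temps), max(temps), by = 0.1)
  if (is.unsorted(temp_grid, strictly = TRUE))
    stop("temp_grid must be strictly increasing")
  C <- cumulative_contrast(cb, temp_grid)
  cref <- cumulative_contrast(cb, reference)
  Cc <- sweep(C, 2L, drop(cref))
  beta_cb <- fit$beta[seq_len(ncb)]
  V_cb <- fit$cov[seq_len(ncb), seq_len(ncb), drop = FALSE]
  log_rr <- drop(Cc %*% beta_cb)
  se <- sqrt(pmax(rowSums((Cc %*% V_cb) * Cc), 0))
  bk <- cb$spline_spec$boundary_knots
  structure(list(temp_grid = temp_grid, log_rr = log_rr, se = se,
                 reference_temp = reference,
                 percentile = 100 * stats::ecdf(temps)(temp_grid),
                 extrapolated = temp_grid < bk[1] | temp_grid > bk[2],
                 temps = temps),
            class = "exposure_response_curve")
}

#' @export
print.exposure_response_curve <- function(x, ...) {
  cat(sprintf("Cumulative exposure-response curve: %d grid points on [%.1f, %.1f] C, reference %.2f C\n",
              length(x$temp_grid), min(x$temp_grid), max(x$temp_grid),
              x$reference_temp))
  invisible(x)
}

#' Empirical minimum mortality temperature
#'
#' Scans the fitted cumulative curve for the grid temperature minimising the
#' cumulative log relative risk within percentile bounds (default 1st-99th,
#' the conventional search range). Ties are broken toward the lower
#' temperature. The percentile scale is the one the curve was built on
#' (warm-season analysis temperatures).
#'
#' @param curve an [cumulative_curve()] result.
#' @param bounds percentile pair, default `c(1, 99)`.
#' @return An object of class `mmt_result`: `mmt_temp`, `mmt_percentile`.
#' @export
find_mmt <- function(curve, bounds = c(1, 99)) {
  stopifnot(inherits(curve, "exposure_response_curve"))
  if (any(bounds <= 0 | bounds >= 100) || bounds[1] >= bounds[2])
    stop("bounds must be an increasing percentile pair inside (0, 100)")
  tb <- stats::quantile(curve$temps, bounds / 100, names = FALSE, type = 7)
  inb <- curve$temp_grid >= tb[1] & curve$temp_grid <= tb[2]
  if (!any(inb))
    stop("find_mmt: the curve grid does not cover the requested bounds")
  g <- curve$temp_grid[inb]
  v <- curve$log_rr[inb]
  mmt <- g[which.min(v)]  # first minimum = coolest under ties
  structure(list(mmt_temp = mmt,
                 mmt_percentile = 100 * stats::ecdf(curve$temps)(mmt)),
            class = "mmt_result")
}

#' Relative risks at temperature percentiles
#'
#' RR and 95 percent Wald confidence interval, `exp(log_rr +/- 1.96 se)`,
#' at the grid temperature nearest each requested percentile of the
#' analysis temperature distribution. The curve must already be centered at
#' the intended reference (normally the city-wide MMT), so the RR at the
#' reference percentile is exactly 1 with a degenerate interval.
#'
#' @param curve an [cumulative_curve()] result.
#' @param percentiles percentages in `[0, 100]` (default `c(90, 99)`,
#'   moderate and extreme heat).
#' @param stratum label carried into the output table.
#' @return An object of class `rr_bundle`: data.frame with `stratum`,
#'   `percentile`, `temp`, `rr`, `ci_low`, `ci_high`.
#' @export
rr_at <- function(curve, percentiles = c(90, 99), stratum = "all") {
  stopifnot(inherits(curve, "exposure_response_curve"))
  if (any(percentiles < 0 | percentiles > 100))
    stop("percentiles must lie in [0, 100]")
  tq <- stats::quantile(curve$temps, percentiles / 100, names = FALSE, type = 7)
  idx <- vapply(tq, function(t) which.min(abs(curve$temp_grid - t)), integer(1))
  lr <- curve$log_rr[idx]
  se <- curve$se[idx]
  out <- data.frame(stratum = stratum, percentile = percentiles,
                    temp = curve$temp_grid[idx],
                    rr = exp(lr),
                    ci_low = exp(lr - 1.96 * se),
                    ci_high = exp(lr + 1.96 * se),
                    stringsAsFactors = FALSE)
  class(out) <- c("rr_bundle", "data.frame")
  out
}
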