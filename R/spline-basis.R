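#' Natural cubic spline specification with percentile-placed knots
#'
#' A `spline_spec` fixes everything needed to rebuild the exposure basis
#' exactly: the internal knots (here, placed at warm-season temperature
#' percentiles) and the boundary knots beyond which the spline is linear.
#' The basis dimension is `length(internal_knots) + 1` (no intercept column;
#' the model intercept lives in the regression design).
#'
#' @param internal_knots numeric vector of internal knot locations (degrees C
#'   for the exposure basis), sorted ascending.
#' @param boundary_knots length-2 numeric vector `(min, max)`; the natural
#'   (second-derivative-zero, linear extrapolation) constraints apply here.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(internal_knots, boundary_knots) {
  internal_knots <- sort(as.numeric(internal_knots))
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || boundary_knots[1] >= boundary_knots[2])
    stop("boundary_knots must be an increasing pair (min, max)")
  if (any(!is.finite(internal_knots)) || any(!is.finite(boundary_knots)))
    stop("spline_spec: knots must be finite")
  if (any(internal_knots <= boundary_knots[1]) ||
      any(internal_knots >= boundary_knots[2]))
    stop("internal knots must lie strictly inside the boundary knots")
  structure(list(internal_knots = internal_knots,
                 boundary_knots = boundary_knots),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural spline spec: internal knots at",
      paste(signif(x$internal_knots, 4), collapse = ", "),
      "| boundary", paste(signif(x$boundary_knots, 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Basis dimension of a spline specification
#' @param spec a [spline_spec()].
#' @return integer, number of basis columns (`internal knots + 1`).
#' @export
spline_df <- function(spec) length(spec$internal_knots) + 1L

#' Empirical percentile knots
#'
#' Computes empirical quantiles by the linear order-statistic interpolation
#' rule (the convention where the p-th quantile of n points interpolates
#' between adjacent order statistics, `stats::quantile` type 7), sorted
#' ascending. Used to place the exposure spline's internal knots at the 50th
#' and 90th percentiles of the analysis temperature distribution.
#'
#' @param values numeric vector, non-empty, finite.
#' @param probs percentages in (0, 100).
#' @return numeric vector of knot values, sorted ascending.
#' @export
percentile_knots <- function(values, probs) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("percentile_knots: empty input")
  if (any(!is.finite(values))) stop("percentile_knots: non-finite values")
  if (any(probs <= 0 | probs >= 100)) stop("probs must be in (0, 100)")
  sort(stats::quantile(values, probs / 100, names = FALSE, type = 7))
}

#' Evaluate the natural cubic spline basis
#'
#' Returns the n x (k + 1) natural cubic spline basis for the given spec
#' (k = number of internal knots): piecewise cubic, C2-continuous at the
#' knots, with zero second derivative at the boundary knots and linear
#' extrapolation beyond them. Rows are independent, so pointwise and
#' vectorised evaluation agree; evaluation is fully determined by the knot
#' specification, which is what lets prediction contrast vectors be rebuilt
#' bit-exactly.
#'
#' @param x numeric vector of evaluation points.
#' @param spec a [spline_spec()].
#' @return numeric matrix, `length(x)` rows and `spline_df(spec)` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  x <- as.numeric(x)
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("ns_basis: non-finite x at indices ",
         paste(utils::head(bad, 10L), collapse = ", "))
  B <- splines::ns(x, knots = spec$internal_knots,
                   Boundary.knots = spec$boundary_knots)
  B <- matrix(as.numeric(B), nrow = length(x))
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}
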