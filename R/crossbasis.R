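#' Lag structure specification
#'
#' The lag dimension of the cross-basis. Only the unconstrained `"strata"`
#' form (one stratum per integer lag, lag basis dimension `max_lag + 1`) is
#' implemented; it is the richest choice for a short 0-3 day window and
#' leaves the within-window lag distribution entirely data-driven.
#'
#' @param max_lag non-negative integer, maximum lag in days (default 3).
#' @param basis_type lag basis family; only `"strata"` is supported.
#' @return An object of class `lag_spec`.
#' @export
lag_spec <- function(max_lag = 3L, basis_type = "strata") {
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 0L) stop("max_lag must be >= 0")
  basis_type <- match.arg(basis_type, "strata")
  structure(list(max_lag = max_lag, basis_type = basis_type),
            class = "lag_spec")
}

#' Lagged exposure matrix
#'
#' Column `l + 1` holds the series shifted by `l` days: the value at day
#' `t - l` aligned to row `t`. The first `max_lag` rows of each contiguous
#' block have incomplete lag history and are masked invalid, never
#' zero-filled. Non-contiguous series must declare their block structure
#' explicitly via `block`.
#'
#' @param x numeric series ordered by contiguous calendar day.
#' @param max_lag non-negative integer.
#' @param block optional vector marking contiguous segments (same length as
#'   `x`); lags never cross block boundaries.
#' @return list with `matrix` (`length(x)` x `max_lag + 1`, columns named
#'   `lag0..lagL`) and `valid` (logical row mask).
#' @export
lag_matrix <- function(x, max_lag, block = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  if (is.null(block)) block <- rep(1L, n)
  if (length(block) != n) stop("block must have the same length as the series")
  L <- matrix(NA_real_, n, max_lag + 1L,
              dimnames = list(NULL, paste0("lag", 0:max_lag)))
  valid <- rep(TRUE, n)
  for (b in unique(block)) {
    idx <- which(block == b)
    m <- length(idx)
    for (l in 0:max_lag) {
      if (l < m) L[idx[(l + 1L):m], l + 1L] <- x[idx[1L:(m - l)]]
    }
    if (max_lag > 0L) valid[idx[seq_len(min(max_lag, m))]] <- FALSE
  }
  list(matrix = L, valid = valid)
}

#' Exposure x lag cross-basis
#'
#' The design-matrix block of the distributed lag non-linear model: for the
#' strata lag basis, the column for exposure basis function j and lag l
#' holds `ns_basis_j(x[t - l])` at row t. Columns are ordered lag-major
#' within exposure (`b1.l0, b1.l1, ..., b1.lL, b2.l0, ...`); prediction
#' contrast vectors must match this order bit-exactly, so it is fixed.
#' Rows with incomplete lag history carry `NA` and are flagged in
#' `valid_row_mask`.
#'
#' @param x exposure series ordered by contiguous calendar day.
#' @param spline_spec a [spline_spec()] for the exposure dimension.
#' @param lag_spec a [lag_spec()].
#' @param block optional contiguous-segment marker, see [lag_matrix()].
#' @return An object of class `cross_basis`: list with `matrix`,
#'   `spline_spec`, `lag_spec`, `valid_row_mask`, and the input series `x`.
#' @export
cross_basis <- function(x, spline_spec, lag_spec = heatparadox::lag_spec(),
                        block = NULL) {
  stopifnot(inherits(spline_spec, "spline_spec"), inherits(lag_spec, "lag_spec"))
  lm_ <- lag_matrix(x, lag_spec$max_lag, block = block)
  L <- lm_$matrix
  nlag <- lag_spec$max_lag + 1L
  dfx <- spline_df(spline_spec)
  CB <- matrix(NA_real_, length(x), dfx * nlag)
  cn <- character(dfx * nlag)
  for (l in seq_len(nlag) - 1L) {
    xl <- L[, l + 1L]
    ok <- !is.na(xl)
    if (any(ok)) {
      Bl <- ns_basis(xl[ok], spline_spec)
      for (j in seq_len(dfx)) CB[ok, (j - 1L) * nlag + l + 1L] <- Bl[, j]
    }
    for (j in seq_len(dfx)) cn[(j - 1L) * nlag + l + 1L] <- sprintf("b%d.l%d", j, l)
  }
  colnames(CB) <- cn
  valid <- lm_$valid & rowSums(is.na(L)) == 0L
  structure(list(matrix = CB, spline_spec = spline_spec, lag_spec = lag_spec,
                 valid_row_mask = valid, x = x),
            class = "cross_basis")
}

#' Cumulative contrast rows for a cross-basis
#'
#' For each temperature in `at`, the vector c(T) whose inner product with the
#' cross-basis coefficients gives the cumulative (summed over lags) log
#' relative risk of sustained exposure at T: the exposure-basis row at T
#' repeated across every lag stratum, in cross-basis column order.
#'
#' @param cb a [cross_basis()].
#' @param at numeric vector of temperatures.
#' @return matrix, `length(at)` rows by `ncol(cb$matrix)` columns.
#' @export
cumulative_contrast <- function(cb, at) {
  stopifnot(inherits(cb, "cross_basis"))
  B <- ns_basis(at, cb$spline_spec)
  nlag <- cb$lag_spec$max_lag + 1L
  C <- matrix(0, length(at), ncol(cb$matrix),
              dimnames = list(NULL, colnames(cb$matrix)))
  for (j in seq_len(ncol(B)))
    for (l in seq_len(nlag) - 1L) C[, (j - 1L) * nlag + l + 1L] <- B[, j]
  C
}
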