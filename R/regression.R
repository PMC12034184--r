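#' Quasi-Poisson regression on a design matrix
#'
#' Log-link Poisson-score GLM fitted by iteratively reweighted least squares
#' (via [stats::glm.fit()], relative deviance tolerance 1e-9, at most 100
#' iterations). Point estimates are identical to Poisson maximum likelihood;
#' the dispersion parameter phi, estimated as Pearson chi-square / (n - p),
#' only scales the covariance: `cov = phi * (X'WX)^-1` at convergence.
#'
#' @param y non-negative count vector (rows with `NA` must be excluded by
#'   the caller; masked cross-basis rows are never valid input here).
#' @param X design matrix, full column rank, including any intercept.
#' @return An object of class `glm_fit`: `beta`, `cov`, `dispersion`,
#'   `n_obs`, `n_params`, `converged`, `n_iter`, `fitted`.
#' @export
fit_quasipoisson <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y and X have different numbers of rows")
  if (anyNA(y) || anyNA(X)) stop("fit_quasipoisson: NA in y or X; drop masked rows first")
  if (any(y < 0)) stop("fit_quasipoisson: negative counts")
  if (nrow(X) <= ncol(X)) stop("fit_quasipoisson: n_obs must exceed n_params")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("fit_quasipoisson: design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-9, maxit = 100))
  if (!fit$converged)
    warning("fit_quasipoisson: IRLS did not converge in 100 iterations")
  beta <- fit$coefficients
  mu <- fit$fitted.values
  W <- fit$weights  # IRLS working weights at convergence (= mu for log link)
  n <- length(y); p <- ncol(X)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  XtWX <- crossprod(X * sqrt(W))
  cov <- phi * chol2inv(chol(XtWX))
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, cov = cov, dispersion = phi,
                 n_obs = n, n_params = p,
                 converged = fit$converged, n_iter = fit$iter, fitted = mu),
            class = "glm_fit")
}

#' Weighted least squares with HC1 robust standard errors
#'
#' The survey estimator: `beta = (X'WX)^-1 X'Wy` with user-supplied
#' probability weights, and the heteroskedasticity-consistent HC1 sandwich
#' covariance (bread `(X'WX)^-1`, meat `sum w_i^2 e_i^2 x_i x_i'`,
#' small-sample factor `n/(n-p)`). Weights enter both the point estimator
#' and the sandwich meat, so rescaling all weights by a positive constant
#' leaves every reported quantity unchanged. Inference uses t with `n - p`
#' degrees of freedom; the overall test is a robust Wald F on all
#' non-intercept coefficients.
#'
#' @param y numeric outcome.
#' @param X design matrix with named columns (intercept included).
#' @param w positive weights; default all 1 (unweighted OLS).
#' @return An object of class `ols_fit`: named `beta`, `robust_se`,
#'   `t_stats`, `p_values`, `cov`, `n_obs`, `r_squared`, `f_stat`,
#'   `f_pvalue`, `residuals`.
#' @export
fit_wls_robust <- function(y, X, w = rep(1, length(y))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- as.numeric(w)
  if (anyNA(y) || anyNA(X) || anyNA(w)) stop("fit_wls_robust: NA input")
  if (any(w <= 0)) stop("fit_wls_robust: weights must be strictly positive")
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || length(w) != n) stop("dimension mismatch")
  qr_x <- qr(X * sqrt(w))
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("fit_wls_robust: design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  e <- y - drop(X %*% beta)
  bread <- chol2inv(chol(crossprod(X * sqrt(w))))
  meat <- crossprod(X * (w * e))
  V <- (n / (n - p)) * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  ybar <- sum(w * y) / sum(w)
  ss_res <- sum(w * e^2)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  # robust Wald F over all non-intercept terms
  keep <- which(!grepl("^\\(?[Ii]ntercept\\)?$", colnames(X)))
  if (length(keep) > 0 && any(se[keep] > 0)) {
    b_r <- beta[keep]
    V_r <- V[keep, keep, drop = FALSE]
    f_stat <- drop(crossprod(b_r, solve(V_r, b_r))) / length(keep)
    f_p <- stats::pf(f_stat, length(keep), n - p, lower.tail = FALSE)
  } else {
    f_stat <- NA_real_; f_p <- NA_real_
  }
  structure(list(beta = beta, robust_se = se, t_stats = tval, p_values = pval,
                 cov = V, n_obs = n, r_squared = r2,
                 f_stat = f_stat, f_pvalue = f_p, residuals = e),
            class = "ols_fit")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing design
#' column j on all the other columns (intercept included as a regressor but
#' excluded from reporting). Perfectly collinear columns are reported as
#' `Inf`.
#'
#' @param X design matrix with an intercept column (named
#'   `(Intercept)` or `intercept`).
#' @return named numeric vector of VIFs for the non-intercept columns.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  icol <- grep("^\\(?[Ii]ntercept\\)?$", colnames(X))
  if (length(icol) != 1L)
    stop("vif: X must contain exactly one intercept column")
  pred <- setdiff(seq_len(ncol(X)), icol)
  out <- vapply(pred, function(j) {
    others <- X[, -j, drop = FALSE]
    f <- stats::lm.fit(others, X[, j])
    e <- f$residuals
    v <- X[, j] - mean(X[, j])
    ss_tot <- sum(v^2)
    if (ss_tot == 0) return(NA_real_)
    r2 <- 1 - sum(e^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)[pred]
  out
}

#' Tidy coefficient table from a robust OLS fit
#'
#' One row per term with estimate, robust SE, t, p and significance stars
#' at the 0.01 / 0.05 / 0.1 levels.
#'
#' @param fit an `ols_fit`.
#' @return data.frame with columns `term`, `estimate`, `robust_se`,
#'   `t`, `p`, `stars`.
#' @export
tidy_ols <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  stars <- ifelse(fit$p_values < 0.01, "***",
           ifelse(fit$p_values < 0.05, "**",
           ifelse(fit$p_values < 0.1, "*", "")))
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             robust_se = unname(fit$robust_se), t = unname(fit$t_stats),
             p = unname(fit$p_values), stars = unname(stars),
             stringsAsFactors = FALSE)
}
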