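# Independent oracles used across the suite. These deliberately avoid the
# package's own construction paths.

# Natural cubic spline via the truncated-power construction: for all knots
# xi_1 < ... < xi_K (boundary + internal), the space is spanned by
# {1, x, d_1(x) - d_{K-1}(x), ..., d_{K-2}(x) - d_{K-1}(x)} with
# d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k).
tp_natural_basis <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  pos3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pos3(x - knots[k]) - pos3(x - knots[K])) /
    (knots[K] - knots[k])
  out <- cbind(1, x)
  for (k in seq_len(K - 2L)) out <- cbind(out, d(k) - d(K - 1L))
  out
}

# Represent a function given by its values at K collocation points as a
# truncated-power natural spline (solved by linear algebra), then evaluate.
tp_interpolate <- function(x_new, knots, x_col, y_col) {
  A <- tp_natural_basis(x_col, knots)
  cf <- solve(A, y_col)
  drop(tp_natural_basis(x_new, knots) %*% cf)
}

# Poisson score-equation solver: straight Newton iterations with analytic
# Hessian, independent of glm.fit's IRLS bookkeeping.
newton_poisson <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y) + 0.5)
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X * mu, X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Explicit-arithmetic HC1 sandwich for weighted least squares.
hc1_oracle <- function(y, X, w) {
  n <- length(y); p <- ncol(X)
  XtWX <- t(X) %*% diag(w) %*% X
  beta <- solve(XtWX, t(X) %*% diag(w) %*% y)
  e <- y - X %*% beta
  meat <- matrix(0, p, p)
  for (i in seq_len(n))
    meat <- meat + (w[i] * e[i])^2 * tcrossprod(X[i, ])
  V <- (n / (n - p)) * solve(XtWX) %*% meat %*% solve(XtWX)
  list(beta = unname(drop(beta)), se = unname(sqrt(diag(V))), V = V)
}

# Sort-and-interpolate quantile (type-7 convention) written out longhand.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small contiguous daily series for pipeline toys.
toy_series <- function(tmean, start = as.Date("2015-04-25"),
                       deaths = rep(10L, length(tmean))) {
  data.frame(date = seq(start, by = "day", length.out = length(tmean)),
             deaths = deaths, tmean = tmean)
}
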