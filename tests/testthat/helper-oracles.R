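# Independent oracles, written as naive scalar arithmetic so they share no
# code path with the package implementations they check.

# Natural cubic spline via the truncated-power representation with the
# natural (linear-tail) constraints, evaluated one point and one column at
# a time with plain if/else arithmetic.
oracle_natural_basis <- function(x, spec) {
  k <- c(spec$boundary[1], spec$knots, spec$boundary[2])
  K <- length(k)
  tp3 <- function(u) if (u > 0) u^3 else 0
  dfun <- function(xi, j) {
    (tp3(xi - k[j]) - tp3(xi - k[K])) / (k[K] - k[j])
  }
  ncol_out <- spec$df
  out <- matrix(NA_real_, length(x), ncol_out)
  for (i in seq_along(x)) {
    cols <- c()
    if (spec$intercept) cols <- c(cols, 1)
    cols <- c(cols, x[i])
    if (K > 2) {
      for (j in 1:(K - 2)) {
        cols <- c(cols, dfun(x[i], j) - dfun(x[i], K - 1))
      }
    }
    out[i, ] <- cols
  }
  out
}

# Cross-basis by a naive triple loop over day, exposure-basis column and
# lag-basis column, summing over lags one scalar at a time.
oracle_crossbasis <- function(x, var_spec, lag_spec, max_lag) {
  n <- length(x)
  V <- heatlag::natural_cubic_basis(x, var_spec)
  W <- heatlag::natural_cubic_basis(0:max_lag, lag_spec)
  Jv <- ncol(V); Jw <- ncol(W)
  out <- matrix(NA_real_, n, Jv * Jw)
  for (t in (max_lag + 1):n) {
    for (j in 1:Jv) {
      for (kk in 1:Jw) {
        s <- 0
        for (l in 0:max_lag) s <- s + V[t - l, j] * W[l + 1, kk]
        out[t, (j - 1) * Jw + kk] <- s
      }
    }
  }
  out
}

# Poisson log-link GLM by straight Newton-Raphson on the score equations.
oracle_newton_glm <- function(y, X, max_iter = 50) {
  p <- ncol(X)
  beta <- c(log(mean(y) + 0.01), rep(0, p - 1))
  for (it in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * mu)
    delta <- solve(H, score)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-12) break
  }
  unname(beta)
}

# Run-length scan marking every day of each qualifying exceedance run.
oracle_run_scan <- function(x, threshold, min_duration) {
  n <- length(x)
  ind <- integer(n)
  i <- 1
  while (i <= n) {
    if (x[i] > threshold) {
      j <- i
      while (j < n && x[j + 1] > threshold) j <- j + 1
      if (j - i + 1 >= min_duration) ind[i:j] <- 1L
      i <- j + 1
    } else i <- i + 1
  }
  ind
}

# Daily attributable fraction by a day-by-day loop: for each fitted day,
# sum the centered contribution of each lagged exposure evaluated through
# the basis functions directly.
oracle_daily_af <- function(fit, mmt) {
  cb <- fit$crossbasis
  theta <- fit$coefficients[fit$labels$crossbasis]
  W <- heatlag::natural_cubic_basis(0:cb$max_lag, cb$lag_spec)
  vm <- drop(heatlag::natural_cubic_basis(mmt, cb$var_spec))
  Jv <- length(vm); Jw <- ncol(W)
  af <- numeric(length(fit$rows))
  for (i in seq_along(fit$rows)) {
    t <- fit$rows[i]
    s <- 0
    for (l in 0:cb$max_lag) {
      vx <- drop(heatlag::natural_cubic_basis(fit$exposure[t - l],
                                              cb$var_spec))
      for (j in 1:Jv) for (kk in 1:Jw)
        s <- s + (vx[j] - vm[j]) * W[l + 1, kk] *
          theta[(j - 1) * Jw + kk]
    }
    af[i] <- 1 - exp(-s)
  }
  af
}
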