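#' @keywords internal
"_PACKAGE"

# Logging goes to stderr; level controlled by option "heatlag.verbose"
# (0 = silent, 1 = warnings/notes, 2 = chatty). Default 1.
hl_log <- function(msg, level = 1L) {
  verb <- getOption("heatlag.verbose", 1L)
  if (verb >= level) message("[heatlag] ", msg)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hl_stop <- function(...) stop(..., call. = FALSE)

# Sample quantile with linear interpolation between order statistics
# (stats type 7) -- the percentile convention used throughout.
hl_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

# Draw n multivariate-normal vectors at (mu, Sigma) via Cholesky with an
# eigenvalue-floor fallback for numerically non-PSD covariances.
hl_mvn_draws <- function(n, mu, Sigma) {
  p <- length(mu)
  A <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(A)) {
    # positive semi-definite (rank-deficient) case: pivoted Cholesky
    Rp <- tryCatch(suppressWarnings(chol(Sigma, pivot = TRUE)),
                   error = function(e) NULL)
    if (!is.null(Rp)) {
      r <- attr(Rp, "rank")
      piv <- attr(Rp, "pivot")
      if (r < p) Rp[(r + 1):p, ] <- 0
      A <- Rp[, order(piv), drop = FALSE]
    } else {
      hl_log("covariance not PSD at machine precision; flooring eigenvalues at 1e-12")
      es <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
      scale <- max(abs(es$values), 1)
      if (any(!is.finite(es$values)) || min(es$values) < -1e-8 * scale)
        hl_stop("covariance matrix is not positive semi-definite after regularization")
      vals <- pmax(es$values, 1e-12)
      A <- t(es$vectors %*% (t(es$vectors) * sqrt(vals)))
    }
  }
  Z <- matrix(stats::rnorm(n * p), nrow = p, ncol = n)
  drop(mu) + t(A) %*% Z   # p x n
}
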