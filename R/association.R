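# Coefficients and covariance of the cross-basis block of a fit.
cb_block <- function(fit) {
  idx <- fit$labels$crossbasis
  if (is.null(idx)) hl_stop("fit carries no cross-basis block")
  list(theta = fit$coefficients[idx],
       V = fit$vcov[idx, idx, drop = FALSE], idx = idx)
}

#' Centered exposure-response prediction
#'
#' Lag-specific log-RR at exposure `x` and lag `l` is
#' `sum_jk (v_j(x) - v_j(center)) * w_k(l) * theta_jk`; the cumulative
#' (lag 0..L) log-RR is its sum over lags, so the cumulative RR is exactly
#' the product of the per-lag RRs. Pointwise variances follow from the
#' delta method on the fitted covariance; 95 percent intervals are
#' `exp(estimate +/- 1.96 * SE)`.
#'
#' @param fit a [fit_dlnm()] result.
#' @param at exposure values to predict at (warned when outside the
#'   observed exposure range).
#' @param center centering exposure value (must lie inside the observed
#'   range); RR = 1 there by construction.
#' @return object of class `exposure_response`: `grid`, `rr_cum`,
#'   `ci_low`, `ci_high`, `se_log_cum`, `rr_lag` (grid x (L+1)),
#'   `rr_lag_low`, `rr_lag_high`, `center`, `max_lag`.
#' @export
predict_rr <- function(fit, at, center) {
  cb <- fit$crossbasis
  blk <- cb_block(fit)
  xr <- range(fit$exposure, na.rm = TRUE)
  if (center < xr[1] || center > xr[2])
    hl_stop("center ", center, " outside observed exposure range [",
            signif(xr[1], 4), ", ", signif(xr[2], 4), "]")
  if (any(at < xr[1] | at > xr[2]))
    hl_log("prediction values outside observed range: linear extrapolation")
  L <- cb$max_lag
  nlag <- L + 1L
  logrr_lag <- se_lag <- matrix(0, length(at), nlag)
  Ccum <- matrix(0, length(at), length(blk$theta))
  for (l in 0:L) {
    Cl <- lag_contrast_matrix(cb, at, center, l)
    logrr_lag[, l + 1] <- drop(Cl %*% blk$theta)
    se_lag[, l + 1] <- sqrt(pmax(rowSums((Cl %*% blk$V) * Cl), 0))
    Ccum <- Ccum + Cl
  }
  logrr_cum <- drop(Ccum %*% blk$theta)
  se_cum <- sqrt(pmax(rowSums((Ccum %*% blk$V) * Ccum), 0))
  z <- stats::qnorm(0.975)
  structure(list(
    grid = at,
    rr_cum = exp(logrr_cum),
    ci_low = exp(logrr_cum - z * se_cum),
    ci_high = exp(logrr_cum + z * se_cum),
    se_log_cum = se_cum,
    rr_lag = exp(logrr_lag),
    rr_lag_low = exp(logrr_lag - z * se_lag),
    rr_lag_high = exp(logrr_lag + z * se_lag),
    center = center, max_lag = L), class = "exposure_response")
}

#' Minimum-risk exposure (MMT) with simulation interval
#'
#' Locates the exposure value minimizing the cumulative (lag 0..L) risk
#' curve on a fixed-step grid spanning a percentile window of the observed
#' exposures, then quantifies uncertainty by redrawing the cross-basis
#' coefficients from their fitted multivariate-normal distribution and
#' recomputing the argmin per draw (2.5th/97.5th percentiles of the draws).
#'
#' @param fit a [fit_dlnm()] result.
#' @param search_range percentile pair bounding the search window
#'   (default 1st to 99th).
#' @param grid_step grid resolution in exposure units (default 0.1).
#' @param n_draws Monte Carlo draws for the interval (default 1000).
#' @param seed RNG seed for the draws.
#' @return list with `mmt`, `ci` (length 2), `degenerate` (flag: curve
#'   numerically flat, MMT reported at the window midpoint), `grid`.
#' @export
find_mmt <- function(fit, search_range = c(1, 99), grid_step = 0.1,
                     n_draws = 1000L, seed = 1L) {
  blk <- cb_block(fit)
  cb <- fit$crossbasis
  lim <- hl_quantile(fit$exposure, search_range / 100)
  grid <- seq(lim[1], lim[2], by = grid_step)
  L <- cb$max_lag
  Ccum <- matrix(0, length(grid), length(blk$theta))
  for (l in 0:L) Ccum <- Ccum + lag_contrast_matrix(cb, grid, grid[1], l)
  curve <- drop(Ccum %*% blk$theta)
  if (max(curve) - min(curve) < 1e-12) {
    mid <- grid[ceiling(length(grid) / 2)]
    return(list(mmt = mid, ci = c(lim[1], lim[2]), degenerate = TRUE,
                grid = grid))
  }
  mmt <- grid[which.min(curve)]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- hl_mvn_draws(n_draws, blk$theta, blk$V)   # p x n_draws
  curves <- Ccum %*% draws                            # grid x n_draws
  mmts <- grid[max.col(-t(curves), ties.method = "first")]
  list(mmt = mmt, ci = unname(hl_quantile(mmts, c(0.025, 0.975))),
       degenerate = FALSE, grid = grid)
}

# Save/restore global RNG state so seeded internals do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Relative risks at percentile contrasts
#'
#' The 1st, 25th, 75th and 99th exposure percentiles (labelled extremely
#' cold, cold, hot, extremely hot) versus the minimum-risk exposure:
#' lag-specific RRs for lags 0..L and the cumulative lag 0..L RR, each with
#' 95 percent CIs.
#'
#' @param fit a [fit_dlnm()] result.
#' @param mmt centering value; computed by [find_mmt()] when `NULL`.
#' @param probs percentiles (percent scale), default `c(1, 25, 75, 99)`.
#' @param seed passed to [find_mmt()] when `mmt` is `NULL`.
#' @return data frame, one row per percentile x lag (lags `"lag0"`..
#'   `"lag3"`, `"lag03"`-style cumulative), with columns `label`,
#'   `percentile`, `exposure`, `lag`, `rr`, `ci_low`, `ci_high`; the MMT
#'   used is attached as attribute `mmt`.
#' @export
rr_at_percentiles <- function(fit, mmt = NULL, probs = c(1, 25, 75, 99),
                              seed = 1L) {
  xv <- fit$exposure[is.finite(fit$exposure)]
  if (max(xv) - min(xv) < 1e-12)
    hl_stop("exposure series is constant; percentiles are degenerate")
  pv <- hl_quantile(xv, probs / 100)
  labels <- c("extremely cold", "cold", "hot", "extremely hot")
  if (length(probs) != 4) labels <- paste0("p", probs)
  if (is.null(mmt)) mmt <- find_mmt(fit, seed = seed)$mmt
  pred <- predict_rr(fit, at = pv, center = mmt)
  L <- pred$max_lag
  rows <- list()
  for (i in seq_along(pv)) {
    for (l in 0:L) {
      rows[[length(rows) + 1]] <- data.frame(
        label = labels[i], percentile = probs[i], exposure = pv[i],
        lag = paste0("lag", l), rr = pred$rr_lag[i, l + 1],
        ci_low = pred$rr_lag_low[i, l + 1],
        ci_high = pred$rr_lag_high[i, l + 1])
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = labels[i], percentile = probs[i], exposure = pv[i],
      lag = paste0("lag0", L), rr = pred$rr_cum[i],
      ci_low = pred$ci_low[i], ci_high = pred$ci_high[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mmt") <- mmt
  out
}
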