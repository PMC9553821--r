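# Centered contribution matrices for attribution. Row t (a fitted day)
# of M[[comp]] carries sum over lags l of
#   I(x_{t-l} in comp range) * (v(x_{t-l}) - v(mmt)) (x) w(l),
# flattened in cross-basis column order, so M %*% theta_cb is the day's
# summed centered log-RR restricted to the component ("cold": lagged
# exposures below the MMT, "heat": above, "total": all).
attribution_matrices <- function(fit, mmt) {
  cb <- fit$crossbasis
  rows <- fit$rows
  L <- cb$max_lag
  x <- fit$exposure
  p <- ncol(cb$matrix)
  M <- list(total = matrix(0, length(rows), p),
            cold = matrix(0, length(rows), p),
            heat = matrix(0, length(rows), p))
  for (l in 0:L) {
    xl <- x[rows - l]
    Cl <- lag_contrast_matrix(cb, xl, mmt, l)
    M$total <- M$total + Cl
    M$cold <- M$cold + Cl * (xl < mmt)
    M$heat <- M$heat + Cl * (xl > mmt)
  }
  M
}

#' Daily attributable fraction (backward perspective)
#'
#' `AF_t = 1 - exp(-sum_{l=0}^{L} b(x_{t-l}, l))`, where `b(x, l)` is the
#' MMT-centered lag-specific log-RR contribution of the exposure observed
#' `l` days before day `t`. Days with incomplete lag history (or missing
#' data) are excluded, matching the rows used in fitting.
#'
#' @param fit a [fit_dlnm()] result.
#' @param mmt the minimum-risk exposure used as reference.
#' @param component `"total"` (default), `"cold"` (contributions from
#'   lagged exposures below the MMT only) or `"heat"` (above only).
#' @return numeric vector of daily AFs, one per fitted day (`fit$rows`).
#' @export
daily_af <- function(fit, mmt, component = c("total", "cold", "heat")) {
  component <- match.arg(component)
  blk <- cb_block(fit)
  M <- attribution_matrices(fit, mmt)[[component]]
  1 - exp(-drop(M %*% blk$theta))
}

#' Total attributable number and fraction
#'
#' `AN = sum_t AF_t * Y_t` over the fitted days; the attributable fraction
#' is `AN / sum_t Y_t`. The cold/heat split zeroes lag contributions from
#' exposures on the other side of the MMT before the AF transform, which
#' makes the decomposition exactly additive whenever each day's
#' contributions are single-signed.
#'
#' @inheritParams daily_af
#' @return list with `an`, `af` (fraction in \[0, 1\), `NA` with
#'   `zero_counts = TRUE` when no events were observed), `component`.
#' @export
total_an <- function(fit, mmt, component = c("total", "cold", "heat")) {
  component <- match.arg(component)
  af <- daily_af(fit, mmt, component)
  tot_y <- sum(fit$y)
  an <- sum(af * fit$y)
  if (tot_y == 0) {
    hl_log("all counts are zero; attributable fraction undefined")
    return(list(an = 0, af = NA_real_, component = component,
                zero_counts = TRUE))
  }
  list(an = an, af = an / tot_y, component = component, zero_counts = FALSE)
}

#' Monte Carlo empirical confidence intervals
#'
#' Draws coefficient vectors from the multivariate normal at the fitted
#' estimates and covariance (Cholesky factorization, fixed seed),
#' re-evaluates a user-supplied statistic on each draw, and reports the
#' 2.5th/97.5th percentiles. The statistic receives the full drawn
#' coefficient vector.
#'
#' @param fit a [fit_dlnm()] (or any `dlnm_fit`) result.
#' @param pipeline function of a coefficient vector returning a numeric
#'   vector (named or not) of statistics.
#' @param n_draws number of replications (default 1000).
#' @param seed RNG seed; identical seeds give bit-identical intervals.
#' @return list with `low`, `high` (per statistic), and `draws`
#'   (statistics x n_draws matrix).
#' @export
mc_eci <- function(fit, pipeline, n_draws = 1000L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- hl_mvn_draws(n_draws, fit$coefficients, fit$vcov)
  stats_mat <- vapply(seq_len(n_draws),
                      function(i) as.numeric(pipeline(draws[, i])),
                      numeric(length(pipeline(fit$coefficients))))
  stats_mat <- matrix(stats_mat, ncol = n_draws)
  list(low = apply(stats_mat, 1, function(v) hl_quantile(v, 0.025)),
       high = apply(stats_mat, 1, function(v) hl_quantile(v, 0.975)),
       draws = stats_mat)
}

#' Attributable burden with empirical confidence intervals
#'
#' Point estimates and Monte Carlo eCIs (1000 coefficient draws by
#' default) of the attributable number and fraction, for the total burden
#' and its cold/heat decomposition. The MMT is held fixed across draws;
#' set `resample_mmt = TRUE` to re-locate it per draw.
#'
#' @inheritParams daily_af
#' @param n_draws number of Monte Carlo replications.
#' @param seed RNG seed.
#' @param resample_mmt recompute the MMT within each draw?
#' @return data frame with one row per component (`total`, `cold`,
#'   `heat`): `an`, `an_low`, `an_high`, `af`, `af_low`, `af_high`;
#'   attributes `mmt`, `n_draws`, `seed`.
#' @export
attribute_burden <- function(fit, mmt, n_draws = 1000L, seed = 1L,
                             resample_mmt = FALSE) {
  blk <- cb_block(fit)
  y <- fit$y
  tot_y <- sum(y)
  M <- attribution_matrices(fit, mmt)
  an_point <- vapply(M, function(m)
    sum(y * (1 - exp(-drop(m %*% blk$theta)))), numeric(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  theta_draws <- hl_mvn_draws(n_draws, blk$theta, blk$V)  # p_cb x n_draws
  if (resample_mmt) {
    grid <- find_mmt(fit, seed = seed)$grid
    Ccum <- matrix(0, length(grid), length(blk$theta))
    for (l in 0:fit$crossbasis$max_lag)
      Ccum <- Ccum + lag_contrast_matrix(fit$crossbasis, grid, grid[1], l)
    mmts <- grid[max.col(-t(Ccum %*% theta_draws), ties.method = "first")]
    an_draws <- vapply(seq_len(n_draws), function(i) {
      Mi <- attribution_matrices(fit, mmts[i])
      vapply(Mi, function(m)
        sum(y * (1 - exp(-drop(m %*% theta_draws[, i])))), numeric(1))
    }, numeric(3))
  } else {
    an_draws <- rbind(
      total = colSums(y * (1 - exp(-(M$total %*% theta_draws)))),
      cold = colSums(y * (1 - exp(-(M$cold %*% theta_draws)))),
      heat = colSums(y * (1 - exp(-(M$heat %*% theta_draws)))))
  }
  ql <- apply(an_draws, 1, function(v) hl_quantile(v, 0.025))
  qh <- apply(an_draws, 1, function(v) hl_quantile(v, 0.975))
  frac <- function(v) if (tot_y > 0) v / tot_y else NA_real_
  out <- data.frame(component = c("total", "cold", "heat"),
                    an = unname(an_point), an_low = unname(ql),
                    an_high = unname(qh),
                    af = frac(unname(an_point)), af_low = frac(unname(ql)),
                    af_high = frac(unname(qh)))
  attr(out, "mmt") <- mmt
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  out
}
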