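#' Model specification for the quasi-Poisson DLNM
#'
#' Collects the exposure choice, cross-basis settings and the adjustment
#' set: a long-term/seasonal time spline (7 df per year by default), day of
#' the week and holiday indicators (always included), natural cubic splines
#' of precipitation and wind (3 df each), optionally relative humidity
#' (3 df) and the 5-level visibility code as dummies. When the exposure is
#' `humidex` or `wbgt`, relative humidity is dropped from the adjustment
#' set to avoid collinearity (it already enters the index).
#'
#' @param exposure one of `"tmin"`, `"tmean"`, `"tmax"`, `"humidex"`,
#'   `"wbgt"`, `"apparent"`, `"effective"`, `"net_effective"`.
#' @param crossbasis a [crossbasis_spec()].
#' @param time_df_per_year df per year for the trend spline; the total is
#'   `round(time_df_per_year * years_elapsed)` at the series end.
#' @param precip_df,wind_df,rh_df covariate spline df.
#' @param include_rh adjust for mean relative humidity?
#' @param visibility_adjust adjust for the ordinal visibility code?
#' @return object of class `model_spec`.
#' @export
model_spec <- function(exposure = "tmean", crossbasis = crossbasis_spec(),
                       time_df_per_year = 7, precip_df = 3L, wind_df = 3L,
                       rh_df = 3L, include_rh = TRUE,
                       visibility_adjust = FALSE) {
  exposure <- match.arg(exposure,
    c("tmin", "tmean", "tmax", "humidex", "wbgt", "apparent", "effective",
      "net_effective"))
  stopifnot(time_df_per_year > 0, precip_df >= 1, wind_df >= 1, rh_df >= 1)
  if (include_rh && exposure %in% c("humidex", "wbgt")) {
    hl_log(paste0("exposure '", exposure,
                  "' already encodes humidity; include_rh forced off"))
    include_rh <- FALSE
  }
  structure(list(exposure = exposure, crossbasis = crossbasis,
                 time_df_per_year = time_df_per_year,
                 precip_df = as.integer(precip_df),
                 wind_df = as.integer(wind_df), rh_df = as.integer(rh_df),
                 include_rh = isTRUE(include_rh),
                 visibility_adjust = isTRUE(visibility_adjust)),
            class = "model_spec")
}

# Natural spline basis for an adjustment covariate. Quantile knots can tie
# on zero-inflated covariates (precipitation); fall back to quantiles of the
# distinct values so the knot sequence stays strictly increasing.
covariate_basis <- function(x, df, name = "covariate") {
  spec <- tryCatch(place_knots(x, df), error = function(e) NULL)
  if (is.null(spec)) {
    ux <- unique(x[is.finite(x)])
    if (length(ux) <= df)
      hl_stop("'", name, "' has too few distinct values for a ", df,
              "-df spline")
    spec <- place_knots(ux, df)
    hl_log(paste0("tied quantile knots for '", name,
                  "'; knots placed on distinct values"), level = 2L)
  }
  natural_cubic_basis(x, spec)
}

#' Assemble the response and design matrix
#'
#' Builds `[intercept | cross-basis | time spline | day-of-week dummies |
#' holiday | precipitation spline | wind spline | RH spline (optional) |
#' visibility dummies (optional)]`, dropping rows with incomplete lag
#' history or missing values from both response and design.
#'
#' @param weather a [weather_series()]; thermal-index exposures are computed
#'   on the fly via [add_thermal_indices()] when absent.
#' @param counts a [count_series()] aligned with `weather`.
#' @param spec a [model_spec()].
#' @return list with `y`, `X`, `labels` (column indices per block),
#'   `crossbasis`, `rows` (row indices of `weather` used), `exposure`
#'   (exposure values, full series), `spec`.
#' @export
build_design <- function(weather, counts, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  d <- as.Date(weather$date)
  if (!all(as.Date(counts$date) == d))
    hl_stop("weather and count series are not date-aligned")
  if (!spec$exposure %in% names(weather))
    weather <- add_thermal_indices(weather)
  if (!spec$exposure %in% names(weather))
    hl_stop("exposure '", spec$exposure, "' not available")
  x <- weather[[spec$exposure]]
  cb <- build_crossbasis(x, spec$crossbasis)

  cal <- calendar_features(weather)
  years_end <- cal$years_elapsed[nrow(cal)]
  time_df <- max(2L, as.integer(round(spec$time_df_per_year * years_end)))
  blocks <- list()
  blocks$crossbasis <- cb$matrix
  blocks$time <- covariate_basis(cal$time_index, time_df, "time")
  colnames(blocks$time) <- paste0("time", seq_len(time_df))
  dow <- stats::model.matrix(~ day_of_week, data = cal)[, -1, drop = FALSE]
  colnames(dow) <- sub("day_of_week", "dow_", colnames(dow))
  blocks$dow <- dow
  blocks$holiday <- matrix(as.numeric(weather$holiday), ncol = 1,
                           dimnames = list(NULL, "holiday"))
  if ("precip" %in% names(weather)) {
    blocks$precip <- covariate_basis(weather$precip, spec$precip_df, "precip")
    colnames(blocks$precip) <- paste0("precip", seq_len(spec$precip_df))
  }
  if ("wind" %in% names(weather)) {
    blocks$wind <- covariate_basis(weather$wind, spec$wind_df, "wind")
    colnames(blocks$wind) <- paste0("wind", seq_len(spec$wind_df))
  }
  if (spec$include_rh) {
    if (!"rh_mean" %in% names(weather))
      hl_stop("include_rh = TRUE but 'rh_mean' is absent")
    blocks$rh <- covariate_basis(weather$rh_mean, spec$rh_df, "rh_mean")
    colnames(blocks$rh) <- paste0("rh", seq_len(spec$rh_df))
  }
  if (spec$visibility_adjust) {
    if (!"visibility" %in% names(weather))
      hl_stop("visibility_adjust = TRUE but 'visibility' is absent")
    vis <- factor(weather$visibility, levels = sort(unique(
      weather$visibility[!is.na(weather$visibility)])))
    vm <- stats::model.matrix(~ vis)[, -1, drop = FALSE]
    # model.matrix drops NA rows; rebuild on the full length
    vfull <- matrix(NA_real_, nrow(weather), ncol(vm),
                    dimnames = list(NULL, sub("^vis", "vis_", colnames(vm))))
    vfull[!is.na(weather$visibility), ] <- vm
    blocks$visibility <- vfull
  }

  X <- cbind("(Intercept)" = 1, do.call(cbind, unname(blocks)))
  labels <- list("(Intercept)" = 1L)
  at <- 1L
  for (nm in names(blocks)) {
    labels[[nm]] <- at + seq_len(ncol(blocks[[nm]]))
    at <- at + ncol(blocks[[nm]])
  }
  colnames(X) <- c("(Intercept)", unlist(lapply(blocks, colnames),
                                         use.names = FALSE))
  keep <- cb$complete_row_mask & stats::complete.cases(X) &
    !is.na(counts$count)
  Xk <- X[keep, , drop = FALSE]
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) {
    aliased <- colnames(Xk)[qx$pivot[(qx$rank + 1):ncol(Xk)]]
    hl_stop("design matrix is rank deficient; aliased column(s): ",
            paste(aliased, collapse = ", "))
  }
  list(y = counts$count[keep], X = Xk, labels = labels, crossbasis = cb,
       rows = which(keep), exposure = x, spec = spec)
}

#' Fit a quasi-Poisson GLM by iteratively reweighted least squares
#'
#' Log-link Poisson score equations solved by IRLS with step-halving,
#' iterated to a relative deviance change below 1e-10 (at most 100
#' iterations). The dispersion is the Pearson statistic divided by the
#' residual degrees of freedom, and the coefficient covariance is
#' `dispersion * (X' W X)^-1` at the converged weights.
#'
#' @param y non-negative integer response.
#' @param X full-column-rank design matrix (including the intercept).
#' @param labels optional list of column-index blocks (kept in the fit).
#' @return object of class `dlnm_fit`: `coefficients`, `vcov`,
#'   `dispersion`, `deviance`, `fitted`, `n_used`, `df_residual`,
#'   `converged`, `iter`, `labels`.
#' @export
fit_quasipoisson <- function(y, X, labels = NULL) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, all(y >= 0))
  dev_fun <- function(mu) {
    r <- y * log(ifelse(y == 0, 1, y / mu)) - (y - mu)
    2 * sum(r)
  }
  mu <- pmax(y, 0) + 0.5
  eta <- log(mu)
  beta <- NULL
  dev <- dev_fun(mu)
  trace <- numeric(0)
  for (it in seq_len(100L)) {
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    qx <- qr(X * sw)
    beta_new <- qr.coef(qx, z * sw)
    if (any(is.na(beta_new)))
      hl_stop("design matrix became rank deficient during IRLS")
    # step-halving against divergence/overflow
    step <- 1
    repeat {
      b_try <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_try <- drop(X %*% b_try)
      if (max(eta_try) < 700) {
        mu_try <- exp(eta_try)
        dev_try <- dev_fun(mu_try)
        if (is.finite(dev_try) && (is.null(beta) || dev_try <= dev + 1e-8))
          break
      }
      step <- step / 2
      if (step < 1e-10) {
        attr(trace, "deviance") <- trace
        hl_stop("IRLS failed to find a decreasing step (iteration ", it, ")")
      }
    }
    beta <- b_try; eta <- eta_try; mu <- mu_try
    trace <- c(trace, dev_try)
    if (abs(dev - dev_try) / (abs(dev_try) + 0.1) < 1e-10) {
      dev <- dev_try
      w <- mu
      qx <- qr(X * sqrt(w))
      R <- qr.R(qx)
      piv <- qx$pivot
      Rinv <- backsolve(R, diag(p))
      XtWXinv <- matrix(0, p, p)
      XtWXinv[piv, piv] <- Rinv %*% t(Rinv)
      dispersion <- sum((y - mu)^2 / mu) / (n - p)
      vc <- dispersion * XtWXinv
      dimnames(vc) <- list(colnames(X), colnames(X))
      return(structure(list(
        coefficients = stats::setNames(drop(beta), colnames(X)),
        vcov = vc, dispersion = dispersion, deviance = dev,
        fitted = mu, n_used = n, df_residual = n - p,
        converged = TRUE, iter = it, labels = labels),
        class = "dlnm_fit"))
    }
    dev <- dev_try
  }
  attr(trace, "deviance") <- trace
  hl_stop("IRLS did not converge in 100 iterations (last deviance ",
          signif(dev, 8), ")")
}

#' Fit the full DLNM
#'
#' Convenience wrapper: [build_design()] then [fit_quasipoisson()], with the
#' cross-basis, exposure series and used rows attached for downstream
#' prediction and attribution.
#'
#' @inheritParams build_design
#' @return a `dlnm_fit` augmented with `crossbasis`, `exposure`, `rows`,
#'   `y`, `spec`.
#' @export
fit_dlnm <- function(weather, counts, spec = model_spec()) {
  des <- build_design(weather, counts, spec)
  fit <- fit_quasipoisson(des$y, des$X, des$labels)
  fit$crossbasis <- des$crossbasis
  fit$exposure <- des$exposure
  fit$rows <- des$rows
  fit$y <- des$y
  fit$spec <- des$spec
  fit
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat("Quasi-Poisson DLNM fit\n")
  cat("  n =", x$n_used, " p =", length(x$coefficients),
      " dispersion =", signif(x$dispersion, 4),
      " deviance =", signif(x$deviance, 6), "\n")
  if (!is.null(x$spec)) cat("  exposure:", x$spec$exposure, "\n")
  invisible(x)
}

#' Generalized cross-validation score
#'
#' `GCV = n * D / (n - p)^2` with `D` the model deviance and `p` the number
#' of fitted coefficients.
#'
#' @param fit a `dlnm_fit`.
#' @return the GCV score.
#' @export
gcv_score <- function(fit) {
  n <- fit$n_used
  p <- length(fit$coefficients)
  if (p >= n) hl_stop("GCV undefined: p >= n")
  n * fit$deviance / (n - p)^2
}

#' Select degrees of freedom by GCV
#'
#' Grid search, one df axis at a time, holding the other axes at the values
#' in `spec`. Within an axis the candidate minimizing GCV wins; ties (to
#' 1e-12 relative) break toward the smaller df. Candidates whose design is
#' rank deficient are skipped; if every candidate on an axis fails, an
#' error is raised.
#'
#' @inheritParams build_design
#' @param candidates named list of numeric grids; names among `var_df`,
#'   `lag_df`, `precip_df`, `wind_df`, `rh_df`, `time_df_per_year`.
#' @return the selected [model_spec()], with attribute `gcv_tables`.
#' @export
select_df_by_gcv <- function(weather, counts, spec = model_spec(),
                             candidates = list(var_df = 4:7)) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  tables <- list()
  for (axis in names(candidates)) {
    grid <- sort(candidates[[axis]])
    scores <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      sp <- spec
      if (axis %in% c("var_df", "lag_df")) {
        cbs <- sp$crossbasis
        if (axis == "var_df")
          sp$crossbasis <- crossbasis_spec(grid[i], cbs$lag_df, cbs$max_lag)
        else sp$crossbasis <- crossbasis_spec(cbs$var_df, grid[i], cbs$max_lag)
      } else sp[[axis]] <- grid[i]
      scores[i] <- tryCatch(
        gcv_score(fit_dlnm(weather, counts, sp)),
        error = function(e) NA_real_)
    }
    if (all(is.na(scores)))
      hl_stop("all candidate df for axis '", axis, "' failed to fit")
    best <- min(scores, na.rm = TRUE)
    # ties (relative 1e-12) break toward the smaller df
    pick <- grid[which(scores <= best * (1 + 1e-12))[1]]
    tables[[axis]] <- data.frame(df = grid, gcv = scores)
    if (axis %in% c("var_df", "lag_df")) {
      cbs <- spec$crossbasis
      spec$crossbasis <- if (axis == "var_df")
        crossbasis_spec(pick, cbs$lag_df, cbs$max_lag)
      else crossbasis_spec(cbs$var_df, pick, cbs$max_lag)
    } else spec[[axis]] <- pick
  }
  attr(spec, "gcv_tables") <- tables
  spec
}
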