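test_that("intercept-only quasi-Poisson recovers log(mean) in closed form", {
  y <- c(3L, 7L, 12L, 5L, 9L, 0L, 4L)
  fit <- fit_quasipoisson(y, matrix(1, length(y), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-10)
})

test_that("coefficients match an independent Newton-Raphson oracle", {
  set.seed(41)
  X <- cbind(1, rnorm(20), runif(20))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rpois(20, exp(0.8 + 0.3 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_quasipoisson(y, X)
  expect_equal(unname(fit$coefficients), oracle_newton_glm(y, X),
               tolerance = 1e-8)
  # and against the standard GLM fitter
  g <- glm(y ~ X[, 2] + X[, 3], family = quasipoisson())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(fit$dispersion, summary(g)$dispersion, tolerance = 1e-4)
})

test_that("standard errors agree with the reference GLM implementation", {
  set.seed(42)
  X <- cbind(1, rnorm(50), rbinom(50, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rpois(50, exp(1 + 0.2 * X[, 2] + 0.3 * X[, 3]))
  fit <- fit_quasipoisson(y, X)
  g <- glm(y ~ X[, -1], family = quasipoisson())
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
  # with dispersion forced to 1 the SEs are plain Poisson GLM SEs
  gp <- glm(y ~ X[, -1], family = poisson())
  expect_equal(unname(sqrt(diag(fit$vcov / fit$dispersion))),
               unname(summary(gp)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("equidispersed data yield a Pearson dispersion near one", {
  set.seed(43)
  y <- rpois(5000, 15.8)
  fit <- fit_quasipoisson(y, matrix(1, 5000, 1,
                                    dimnames = list(NULL, "(Intercept)")))
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
})

test_that("permuting design columns permutes coefficients identically", {
  set.seed(44)
  X <- cbind(1, rnorm(40), runif(40), rbinom(40, 1, 0.5))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- rpois(40, exp(1 + 0.1 * X[, 2]))
  fit1 <- fit_quasipoisson(y, X)
  perm <- c(3, 1, 4, 2)
  fit2 <- fit_quasipoisson(y, X[, perm])
  expect_equal(fit2$coefficients[colnames(X)], fit1$coefficients,
               tolerance = 1e-10)
})

test_that("design assembly drops lag-incomplete rows and sizes the trend spline", {
  fx <- generate_fixture("standard")
  w730 <- validate_weather_series(fx$weather[1:730, ])
  c730 <- count_series(w730$date, fx$counts$count[1:730])
  des <- build_design(w730, c730, model_spec())
  expect_equal(length(des$y), 730 - 3)
  expect_equal(length(des$labels$time), 14)  # round(7 * 729/365.25)
  expect_equal(length(des$labels$crossbasis), 6 * 3)
  expect_equal(length(des$labels$dow), 6)
  expect_equal(length(des$labels$holiday), 1)
})

test_that("visibility adjustment adds level-coded indicators (reference 0)", {
  fx <- generate_fixture("standard")
  w <- validate_weather_series(fx$weather[1:730, ])
  cnt <- count_series(w$date, fx$counts$count[1:730])
  des <- build_design(w, cnt, model_spec(visibility_adjust = TRUE))
  expect_equal(length(des$labels$visibility),
               length(unique(w$visibility)) - 1)
})

test_that("humidity adjustment is forced off for humidity-bearing exposures", {
  expect_message(sp <- model_spec(exposure = "humidex", include_rh = TRUE),
                 "include_rh")
  expect_false(sp$include_rh)
  sp2 <- model_spec(exposure = "tmean", include_rh = TRUE)
  expect_true(sp2$include_rh)
})

test_that("rank-deficient designs are rejected listing aliased columns", {
  fx <- generate_fixture("standard")
  w <- validate_weather_series(fx$weather[1:600, ])
  w$holiday <- 0L  # a zero holiday column is aliased with nothing to explain
  cnt <- count_series(w$date, fx$counts$count[1:600])
  expect_error(build_design(w, cnt, model_spec()), "holiday")
})

test_that("GCV follows n*D/(n-p)^2 and its limiting behaviour", {
  mk <- function(n, D, p) structure(list(n_used = n, deviance = D,
                                         coefficients = numeric(p)),
                                    class = "dlnm_fit")
  expect_equal(gcv_score(mk(100, 120, 10)), 100 * 120 / 90^2,
               tolerance = 1e-12)
  expect_lt(gcv_score(mk(100, 110, 10)), gcv_score(mk(100, 120, 10)))
  expect_equal(gcv_score(mk(100, 120, 99)), 100 * 120, tolerance = 1e-12)
  expect_error(gcv_score(mk(100, 120, 100)), "p >= n")
})

test_that("GCV selection returns the grid minimizer (singleton unchanged)", {
  fx <- generate_fixture("standard")
  w <- validate_weather_series(fx$weather[1:900, ])
  cnt <- count_series(w$date, fx$counts$count[1:900])
  sp <- select_df_by_gcv(w, cnt, model_spec(),
                         candidates = list(lag_df = 3))
  expect_equal(sp$crossbasis$lag_df, 3L)
  sp2 <- select_df_by_gcv(w, cnt, model_spec(),
                          candidates = list(var_df = c(4, 6)))
  g4 <- gcv_score(fit_dlnm(w, cnt, model_spec(crossbasis = crossbasis_spec(4))))
  g6 <- gcv_score(fit_dlnm(w, cnt, model_spec(crossbasis = crossbasis_spec(6))))
  expect_equal(sp2$crossbasis$var_df, if (g4 <= g6) 4L else 6L)
  tab <- attr(sp2, "gcv_tables")$var_df
  expect_equal(tab$gcv, c(g4, g6), tolerance = 1e-10)
})
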