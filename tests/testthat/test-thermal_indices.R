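test_that("saturation vapor pressure follows the Magnus form", {
  expect_equal(saturation_vapor_pressure(0), 6.112, tolerance = 1e-12)
  expect_equal(saturation_vapor_pressure(20),
               6.112 * exp(17.67 * 20 / (20 + 243.5)), tolerance = 1e-12)
  Tgrid <- seq(-40, 50, by = 0.5)
  es <- saturation_vapor_pressure(Tgrid)
  expect_true(all(es > 0))
  expect_true(all(diff(es) > 0))
})

test_that("vapor pressure scales linearly with relative humidity", {
  expect_equal(vapor_pressure_from_rh(20, 0), 0)
  expect_equal(vapor_pressure_from_rh(20, 100),
               saturation_vapor_pressure(20), tolerance = 1e-12)
  expect_equal(vapor_pressure_from_rh(20, 50),
               saturation_vapor_pressure(20) / 2, tolerance = 1e-12)
  expect_error(vapor_pressure_from_rh(20, 120), "RH")
  expect_error(vapor_pressure_from_rh(20, -5), "RH")
})

test_that("humidex evaluates its formula and is the identity at vp = 10", {
  expect_equal(humidex(30, 10), 30.0)
  expect_equal(humidex(25, 25), 25 + 0.5555 * 15, tolerance = 1e-12)
  expect_equal(humidex(-5, 2), -5 + 0.5555 * (-8), tolerance = 1e-12)
  set.seed(11)
  Tr <- runif(50, -20, 45)
  expect_equal(humidex(Tr, 10), Tr, tolerance = 1e-14)
})

test_that("wbgt additive form is affine; literal form flags the typo reading", {
  expect_equal(wbgt(0, 0, vp_unit = "mmHg"), 3.94)
  expect_equal(wbgt(30, 20, vp_unit = "mmHg"),
               0.567 * 30 + 0.393 * 20 + 3.94, tolerance = 1e-12)
  lit <- wbgt(30, 20, form = "literal_product", vp_unit = "mmHg")
  expect_equal(lit, 0.567 * 30 * 0.393 * 20 * 3.94, tolerance = 1e-12)
  expect_gt(lit, 100)  # physically absurd as a deg-C index
  # affine in each argument: second differences vanish
  d2T <- wbgt(32, 5, vp_unit = "mmHg") - 2 * wbgt(31, 5, vp_unit = "mmHg") +
    wbgt(30, 5, vp_unit = "mmHg")
  d2v <- wbgt(30, 7, vp_unit = "mmHg") - 2 * wbgt(30, 6, vp_unit = "mmHg") +
    wbgt(30, 5, vp_unit = "mmHg")
  expect_equal(d2T, 0, tolerance = 1e-12)
  expect_equal(d2v, 0, tolerance = 1e-12)
  # hPa input is converted with 1 mmHg = 1.333224 hPa
  expect_equal(wbgt(30, 20 * 1.333224), wbgt(30, 20, vp_unit = "mmHg"),
               tolerance = 1e-12)
})

test_that("auxiliary indices follow their standard forms", {
  expect_equal(as.numeric(auxiliary_indices(20, 10, 0, "apparent")), 19.3,
               tolerance = 1e-12)
  a0 <- as.numeric(auxiliary_indices(20, 10, 0, "apparent"))
  a1 <- as.numeric(auxiliary_indices(20, 10, 3.6, "apparent"))
  expect_equal(a1 - a0, -0.70, tolerance = 1e-12)
  # Missenard effective temperature equals T at saturation
  for (T in c(0, 15, 30)) {
    vp_sat <- saturation_vapor_pressure(T)
    expect_equal(as.numeric(auxiliary_indices(T, vp_sat, 0, "effective")), T,
                 tolerance = 1e-9)
  }
  expect_true(attr(auxiliary_indices(20, 10, 0, "net_effective"),
                   "provisional"))
})

test_that("index operations are elementwise (vectorized equals scalar loop)", {
  set.seed(21)
  T <- runif(40, -10, 42); RH <- runif(40, 5, 95); wind <- runif(40, 0, 30)
  vp <- vapor_pressure_from_rh(T, RH)
  vec <- list(humidex(T, vp), wbgt(T, vp),
              as.numeric(auxiliary_indices(T, vp, wind, "apparent")),
              as.numeric(auxiliary_indices(T, vp, wind, "net_effective")))
  for (i in seq_along(T)) {
    expect_equal(vec[[1]][i], humidex(T[i], vp[i]))
    expect_equal(vec[[2]][i], wbgt(T[i], vp[i]))
    expect_equal(vec[[3]][i],
                 as.numeric(auxiliary_indices(T[i], vp[i], wind[i], "apparent")))
    expect_equal(vec[[4]][i],
                 as.numeric(auxiliary_indices(T[i], vp[i], wind[i],
                                              "net_effective")))
  }
})

test_that("add_thermal_indices appends the index columns", {
  fx <- generate_fixture("tiny")
  w <- add_thermal_indices(fx$weather)
  expect_true(all(c("humidex", "wbgt", "apparent", "effective",
                    "net_effective", "apparent_max") %in% names(w)))
  expect_equal(w$humidex,
               humidex(w$tmean, vapor_pressure_from_rh(w$tmean, w$rh_mean)))
})
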