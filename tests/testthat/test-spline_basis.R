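test_that("knots are placed at equally spaced quantiles", {
  x <- 0:100
  s2 <- place_knots(x, 2)
  expect_equal(s2$knots, 50)
  expect_equal(s2$boundary, c(0, 100))
  s6 <- place_knots(x, 6)
  expect_length(s6$knots, 5)
  expect_equal(s6$knots,
               unname(quantile(x, (1:5) / 6, type = 7)), tolerance = 1e-12)
  expect_error(place_knots(rep(3, 50), 3), "distinct")
})

test_that("linear functions lie in the span of the natural basis", {
  set.seed(31)
  x <- sort(runif(80, -5, 40))
  B <- natural_cubic_basis(x, place_knots(x, 5))
  for (ab in list(c(2, 0), c(-1, 3), c(0.5, -0.7))) {
    y <- ab[1] + ab[2] * x
    res <- resid(lm(y ~ B))
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("basis columns are linear beyond the boundary knots", {
  x <- sort(runif(60, 0, 10))
  spec <- place_knots(x, 4)
  xo <- c(seq(-8, -2, by = 0.5), seq(12, 20, by = 0.5))
  B <- natural_cubic_basis(xo, spec)
  # second finite differences on each tail separately
  left <- 1:13; right <- 14:30
  for (j in seq_len(ncol(B))) {
    for (idx in list(left, right)) {
      b <- B[idx, j]
      d2 <- b[-(1:2)] - 2 * b[-c(1, length(b))] + b[-((length(b) - 1):length(b))]
      expect_lt(max(abs(d2)), 1e-8)
    }
  }
})

test_that("basis values match the truncated-power oracle", {
  set.seed(32)
  x <- runif(200, -10, 45)
  for (spec in list(place_knots(x, 6), place_knots(x, 3),
                    place_knots(0:3, 3, intercept = TRUE))) {
    pts <- seq(min(x) - 2, max(x) + 2, length.out = 20)
    expect_equal(natural_cubic_basis(pts, spec),
                 oracle_natural_basis(pts, spec),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("spline_spec rejects non-increasing knots", {
  expect_error(spline_spec(4, c(5, 3), c(0, 10)), "increasing")
  expect_error(spline_spec(4, c(3, 3), c(0, 10)), "increasing")
  expect_error(spline_spec(4, c(3, 11), c(0, 10)), "increasing")
})

test_that("cross-basis equals the naive triple-loop oracle", {
  set.seed(33)
  x <- runif(30, -5, 40)
  spec <- crossbasis_spec(4, 3, 3)
  cb <- build_crossbasis(x, spec)
  orc <- oracle_crossbasis(x, cb$var_spec, cb$lag_spec, 3)
  keep <- cb$complete_row_mask
  expect_equal(cb$matrix[keep, ], orc[keep, ], ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(which(!cb$complete_row_mask), 1:3)
})

test_that("constant exposure factorizes the cross-basis row", {
  cvals <- 17.3
  x <- c(rep(cvals, 40))
  spec <- crossbasis_spec(4, 3, 3,
                          var_knots = c(10, 15, 20),
                          var_boundary = c(-5, 40))
  cb <- build_crossbasis(x, spec)
  v <- drop(natural_cubic_basis(cvals, cb$var_spec))
  W <- natural_cubic_basis(0:3, cb$lag_spec)
  expected <- as.vector(t(outer(v, colSums(W))))
  for (t in which(cb$complete_row_mask))
    expect_equal(unname(cb$matrix[t, ]), expected, tolerance = 1e-12)
})

test_that("a constant lag basis reduces cross-basis columns to moving sums", {
  set.seed(34)
  x <- runif(50, 0, 30)
  cb <- build_crossbasis(x, crossbasis_spec(4, 1, 3))
  V <- natural_cubic_basis(x, cb$var_spec)
  for (t in 4:50) {
    for (j in 1:4) {
      expect_equal(unname(cb$matrix[t, j]), sum(V[t - 0:3, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-basis is linear in the exposure basis", {
  set.seed(35)
  x <- runif(40, -5, 40)
  spec <- crossbasis_spec(5, 3, 3)
  cb <- build_crossbasis(x, spec)
  V <- natural_cubic_basis(x, cb$var_spec)
  W <- natural_cubic_basis(0:3, cb$lag_spec)
  # assemble the cross-basis by direct summation from a doubled exposure
  # basis; it must equal exactly twice the package matrix
  n <- length(x); Jv <- ncol(V); Jw <- ncol(W)
  doubled <- matrix(0, n, Jv * Jw)
  for (t in 4:n) for (j in 1:Jv) for (k in 1:Jw)
    doubled[t, (j - 1) * Jw + k] <-
      sum(2 * V[t - 0:3, j] * W[1:4, k])
  keep <- cb$complete_row_mask
  expect_equal(doubled[keep, ], 2 * cb$matrix[keep, ], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("series shorter than the lag window is rejected", {
  expect_error(build_crossbasis(c(1, 2, 3), crossbasis_spec(4, 3, 3)),
               "exceed")
})
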