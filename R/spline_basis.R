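#' Natural cubic spline specification
#'
#' Describes a natural cubic spline basis: `df` columns, interior knots
#' strictly inside the boundary knots, and whether the constant function is
#' included. With `intercept = FALSE` the basis spans the natural-spline
#' space minus the constant, so `df` columns require `df - 1` interior
#' knots; with `intercept = TRUE`, `df - 2`.
#'
#' @param df number of basis columns (positive integer).
#' @param knots ordered interior knot values.
#' @param boundary length-2 vector of boundary knots.
#' @param intercept include the constant column?
#' @return object of class `spline_spec`.
#' @export
spline_spec <- function(df, knots, boundary, intercept = FALSE) {
  knots <- as.numeric(knots)
  boundary <- as.numeric(boundary)
  stopifnot(length(boundary) == 2, df >= 1)
  allk <- c(boundary[1], knots, boundary[2])
  if (any(diff(allk) <= 0))
    hl_stop("knots must be strictly increasing and strictly inside the boundary")
  # df = 1 with intercept: constant-only basis (lag stratification collapses
  # to a plain moving sum); no knots involved
  expected <- if (intercept && df == 1) {
    if (length(knots)) hl_stop("constant-only basis takes no interior knots")
    1
  } else length(knots) + 2 - !intercept
  if (df != expected)
    hl_stop("df = ", df, " inconsistent with ", length(knots),
            " interior knots (expected df = ", expected, ")")
  structure(list(df = as.integer(df), knots = knots, boundary = boundary,
                 intercept = isTRUE(intercept)),
            class = "spline_spec")
}

#' Place knots at equally spaced quantiles
#'
#' Interior knots at the `1/(m+1) .. m/(m+1)` quantiles of `x` (linear
#' interpolation between order statistics), boundary knots at the range,
#' where `m = df - 1 - intercept` is the interior-knot count.
#'
#' @param x numeric data the basis will be evaluated on.
#' @param df number of basis columns.
#' @param intercept include the constant column?
#' @return a [spline_spec()].
#' @export
place_knots <- function(x, df, intercept = FALSE) {
  x <- x[is.finite(x)]
  if (length(unique(x)) <= df)
    hl_stop("need more than df = ", df, " distinct values to place knots")
  m <- if (intercept && df == 1) 0L else df - 1L - as.integer(intercept)
  if (m < 0) hl_stop("df too small for intercept = TRUE")
  kn <- if (m > 0) hl_quantile(x, seq_len(m) / (m + 1)) else numeric(0)
  spline_spec(df, kn, range(x), intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Truncated-power parameterization with the natural (linear-tail)
#' constraints built in. Writing the full knot sequence
#' `k_1 < ... < k_K` (boundary plus interior) and
#' `d_j(x) = ((x - k_j)_+^3 - (x - k_K)_+^3) / (k_K - k_j)`,
#' the columns are `1` (if `intercept`), `x`, then
#' `d_j(x) - d_{K-1}(x)` for `j = 1 .. K-2`. Each column is cubic between
#' knots, C2 everywhere and exactly linear beyond the boundary knots;
#' evaluation outside the boundary is therefore linear extrapolation.
#'
#' @param x evaluation points.
#' @param spec a [spline_spec()].
#' @return matrix with `length(x)` rows and `spec$df` columns.
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (spec$intercept && spec$df == 1)
    return(matrix(1, length(x), 1, dimnames = list(NULL, "b1")))
  k <- c(spec$boundary[1], spec$knots, spec$boundary[2])
  K <- length(k)
  dj <- function(j) {
    (pmax(x - k[j], 0)^3 - pmax(x - k[K], 0)^3) / (k[K] - k[j])
  }
  cols <- list()
  if (spec$intercept) cols <- c(cols, list(rep(1, length(x))))
  cols <- c(cols, list(x))
  if (K > 2) {
    dlast <- dj(K - 1)
    for (j in seq_len(K - 2)) cols <- c(cols, list(dj(j) - dlast))
  }
  B <- do.call(cbind, cols)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

#' Cross-basis specification for a distributed-lag nonlinear model
#'
#' Pairs an exposure-dimension spline (default 6 df, no intercept) with a
#' lag-dimension spline evaluated on the integer lag grid `0..max_lag`
#' (default 3 df with intercept, maximum lag 3 days). The total number of
#' cross-basis columns is `var_df * lag_df`.
#'
#' @param var_df exposure-dimension degrees of freedom.
#' @param lag_df lag-dimension degrees of freedom (intercept included).
#' @param max_lag maximum lag in days (>= 1).
#' @param var_knots,var_boundary optional fixed exposure knots; placed from
#'   the data by [build_crossbasis()] when absent.
#' @return object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(var_df = 6L, lag_df = 3L, max_lag = 3L,
                            var_knots = NULL, var_boundary = NULL) {
  stopifnot(max_lag >= 1, var_df >= 1, lag_df >= 1)
  var_spec <- if (!is.null(var_knots) && !is.null(var_boundary))
    spline_spec(var_df, var_knots, var_boundary, intercept = FALSE) else NULL
  lag_spec <- place_knots(0:max_lag, lag_df, intercept = TRUE)
  structure(list(var_df = as.integer(var_df), lag_df = as.integer(lag_df),
                 max_lag = as.integer(max_lag),
                 var_spec = var_spec, lag_spec = lag_spec),
            class = "crossbasis_spec")
}

#' Build the exposure-by-lag cross-basis matrix
#'
#' Row `t` (for complete rows, i.e. `t > max_lag`) has entry `(j, k)`
#' equal to `sum_{l=0}^{L} v_j(x[t-l]) * w_k(l)`, where `v` are the
#' exposure-basis and `w` the lag-basis functions. The first `max_lag`
#' rows have incomplete lag history and are masked (set to `NA`); rows
#' whose lag window touches a missing exposure are likewise masked.
#'
#' @param x exposure series (numeric vector, length > `max_lag`).
#' @param spec a [crossbasis_spec()]; exposure knots are placed at equally
#'   spaced quantiles of `x` if not already fixed.
#' @return object of class `crossbasis`: list with `matrix`
#'   (`length(x)` by `var_df*lag_df`, columns `v{j}.l{k}`),
#'   `complete_row_mask`, `var_spec`, `lag_spec`, `max_lag`, `x`.
#' @export
build_crossbasis <- function(x, spec = crossbasis_spec()) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x)
  L <- spec$max_lag
  if (n <= L) hl_stop("series length ", n, " must exceed max_lag = ", L)
  var_spec <- spec$var_spec %||% place_knots(x, spec$var_df)
  V <- natural_cubic_basis(x, var_spec)              # n x Jv
  W <- natural_cubic_basis(0:L, spec$lag_spec)       # (L+1) x Jw
  Jv <- ncol(V); Jw <- ncol(W)
  CB <- matrix(0, n, Jv * Jw)
  for (l in 0:L) {
    Vl <- rbind(matrix(NA_real_, l, Jv),
                V[seq_len(n - l), , drop = FALSE])
    for (j in seq_len(Jv)) {
      idx <- (j - 1) * Jw + seq_len(Jw)
      CB[, idx] <- CB[, idx] + outer(Vl[, j], W[l + 1, ])
    }
  }
  colnames(CB) <- as.vector(t(outer(seq_len(Jv), seq_len(Jw),
                                    function(j, k) paste0("v", j, ".l", k))))
  mask <- !apply(is.na(CB), 1, any)
  mask[seq_len(L)] <- FALSE
  structure(list(matrix = CB, complete_row_mask = mask,
                 var_spec = var_spec, lag_spec = spec$lag_spec,
                 max_lag = L, spec = spec, x = x),
            class = "crossbasis")
}

# One cross-basis row for a constant exposure held at x0 across the whole
# lag window: sum_l outer(v(x0), w(l)), flattened in the column order of
# build_crossbasis. Used for centering at the MMT.
crossbasis_row_at <- function(cb, x0) {
  v <- natural_cubic_basis(x0, cb$var_spec)
  W <- natural_cubic_basis(0:cb$max_lag, cb$lag_spec)
  as.vector(t(outer(drop(v), colSums(W))))
}

# Per-lag contrast block: matrix (length(x) rows, Jv*Jw cols) whose row i
# carries (v(x_i) - v(center)) (x) w(l) for one fixed lag l.
lag_contrast_matrix <- function(cb, x, center, l) {
  V <- natural_cubic_basis(x, cb$var_spec)
  vc <- drop(natural_cubic_basis(center, cb$var_spec))
  Vd <- sweep(V, 2, vc)
  w <- drop(natural_cubic_basis(l, cb$lag_spec))
  Jv <- ncol(V); Jw <- length(w)
  out <- matrix(0, length(x), Jv * Jw)
  for (j in seq_len(Jv))
    out[, (j - 1) * Jw + seq_len(Jw)] <- outer(Vd[, j], w)
  out
}
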