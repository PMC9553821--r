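#' Simulation configuration for the synthetic arid-climate generator
#'
#' Defaults emulate a desert-margin city in the 19 C annual-mean band:
#' strongly seasonal mean temperature (annual cycle plus AR(1) noise whose
#' realized range spans roughly -10..45 C across tmin..tmax), relative
#' humidity anticorrelated with temperature, gamma-distributed wind around
#' 10 km/h, zero-inflated gamma precipitation averaging 0.5 mm/day, and a
#' diurnal range near 13 C splitting tmean into tmin/tmax.
#'
#' @param n_days series length in days (>= 400 for the default model df).
#' @param start_date first calendar date.
#' @param seed RNG seed; the series is fully determined by it.
#' @param climate list overriding any of: `annual_mean`, `amplitude`,
#'   `peak_doy` (day of year of the warm peak), `ar1`, `noise_sd`
#'   (AR(1) innovation SD, deg C), `diurnal_mean`, `diurnal_sd`,
#'   `rh_intercept`, `rh_slope`, `rh_sd` (RH = intercept + slope*tmean +
#'   noise, clipped to \[2, 100\]), `rh_halfspread` (rh_min/rh_max offset),
#'   `precip_p_wet`, `precip_shape`, `precip_scale`, `wind_shape`,
#'   `wind_scale`, `p_holiday`, `p_visibility` (probabilities of codes
#'   0..4).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_days = 2300L, start_date = "2011-03-21",
                              seed = 1L, climate = list()) {
  if (n_days < 400) hl_stop("n_days must be >= 400 for default model df")
  cl <- list(annual_mean = 19.0, amplitude = 13.0, peak_doy = 197,
             ar1 = 0.7, noise_sd = 1.8,
             diurnal_mean = 13.0, diurnal_sd = 2.0,
             rh_intercept = 63.8, rh_slope = -1.40, rh_sd = 6.0,
             rh_halfspread = 16.0,
             precip_p_wet = 0.12, precip_shape = 0.6, precip_scale = 7.0,
             wind_shape = 7.45, wind_scale = 1.355,
             p_holiday = 0.07,
             p_visibility = c(0.75, 0.12, 0.08, 0.035, 0.015))
  stopifnot(all(names(climate) %in% names(cl)))
  cl[names(climate)] <- climate
  if (cl$ar1 < 0 || cl$ar1 >= 1) hl_stop("AR(1) coefficient must be in [0,1)")
  structure(list(n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 seed = as.integer(seed), climate = cl),
            class = "simulation_config")
}

#' Ground-truth data-generating process for daily counts
#'
#' Log daily rate = baseline + linear trend + day-of-week + holiday +
#' a V-shaped cumulative temperature effect distributed over lags 0..3 +
#' an optional added effect on heat-wave days. The V-shape
#' `v(x) = cold_slope*(x0 - x)_+ + heat_slope*(x - x0)_+` is piecewise
#' linear so the truth has a closed form independent of any spline basis.
#' Defaults place the vertex at 13.8 C with cumulative slopes 0.0289 (cold)
#' and 0.0221 (heat) per degree and lag weights (0.50, 0.24, 0.12, 0.14),
#' a trend of 0.14/year, a holiday offset of -0.05 and overdispersion 1.3.
#'
#' @param baseline_log_rate log baseline daily rate (default `log(15.8)`).
#' @param trend_per_year linear log-rate trend per year.
#' @param dow_effects 7 log-rate offsets (Mon..Sun).
#' @param holiday_effect log-rate offset on holidays.
#' @param vertex,cold_slope,heat_slope V-shape vertex (deg C) and
#'   cumulative log-RR slopes per degree (both >= 0).
#' @param lag_weights 4 non-negative weights over lags 0..3, summing to 1.
#' @param hw_added_effect added log-rate on heat-wave days (default 0).
#' @param overdispersion variance/mean ratio (>= 1; 1 = Poisson).
#' @return object of class `true_dgp`.
#' @export
true_dgp <- function(baseline_log_rate = log(15.8), trend_per_year = 0.14,
                     dow_effects = c(0.01, 0, 0, -0.005, -0.05, 0.01, 0.015),
                     holiday_effect = -0.05, vertex = 13.8,
                     cold_slope = 0.0289, heat_slope = 0.0221,
                     lag_weights = c(0.50, 0.24, 0.12, 0.14),
                     hw_added_effect = 0, overdispersion = 1.3) {
  stopifnot(length(dow_effects) == 7, length(lag_weights) == 4,
            all(lag_weights >= 0), cold_slope >= 0, heat_slope >= 0,
            overdispersion >= 1)
  if (abs(sum(lag_weights) - 1) > 1e-8)
    hl_stop("lag_weights must sum to 1 (cumulative effect identifiability)")
  structure(list(baseline_log_rate = baseline_log_rate,
                 trend_per_year = trend_per_year,
                 dow_effects = dow_effects,
                 holiday_effect = holiday_effect,
                 vertex = vertex, cold_slope = cold_slope,
                 heat_slope = heat_slope, lag_weights = lag_weights,
                 hw_added_effect = hw_added_effect,
                 overdispersion = overdispersion),
            class = "true_dgp")
}

# The DGP's cumulative V-shaped log-RR at exposure x, relative to the vertex.
vshape <- function(dgp, x) {
  dgp$cold_slope * pmax(dgp$vertex - x, 0) +
    dgp$heat_slope * pmax(x - dgp$vertex, 0)
}

#' Simulate a daily weather series
#'
#' Mean temperature is an annual sinusoid plus AR(1) noise; tmin/tmax are
#' tmean minus/plus half a (positive) diurnal range; relative humidity is a
#' clipped linear function of tmean plus noise; precipitation is
#' zero-inflated gamma; wind is gamma; holidays and visibility codes are
#' drawn at fixed probabilities. Fully determined by the seed.
#'
#' @param config a [simulation_config()].
#' @return a [weather_series()].
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  cl <- config$climate
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cl$annual_mean +
    cl$amplitude * cos(2 * pi * (doy - cl$peak_doy) / 365.25)
  ar <- as.numeric(stats::filter(stats::rnorm(n, 0, cl$noise_sd), cl$ar1,
                                 method = "recursive"))
  tmean <- seasonal + ar
  diurnal <- pmax(stats::rnorm(n, cl$diurnal_mean, cl$diurnal_sd), 1)
  tmin <- tmean - diurnal / 2
  tmax <- tmean + diurnal / 2
  rh_mean <- pmin(pmax(cl$rh_intercept + cl$rh_slope * tmean +
                         stats::rnorm(n, 0, cl$rh_sd), 2), 100)
  rh_min <- pmax(rh_mean - cl$rh_halfspread, 0)
  rh_max <- pmin(rh_mean + cl$rh_halfspread, 100)
  wet <- stats::rbinom(n, 1, cl$precip_p_wet)
  precip <- wet * stats::rgamma(n, cl$precip_shape, scale = cl$precip_scale)
  wind <- stats::rgamma(n, cl$wind_shape, scale = cl$wind_scale)
  visibility <- sample(0:4, n, replace = TRUE, prob = cl$p_visibility)
  holiday <- stats::rbinom(n, 1, cl$p_holiday)
  weather_series(date = dates, tmin = tmin, tmean = tmean, tmax = tmax,
                 rh_min = rh_min, rh_mean = rh_mean, rh_max = rh_max,
                 wind = wind, precip = precip, visibility = visibility,
                 holiday = holiday)
}

#' Simulate daily counts under a known data-generating process
#'
#' `log mu_t = baseline + trend + dow + holiday +
#' sum_l lag_weights[l] * v(x_{t-l})` (the first `max_lag` days use the
#' shorter available history), plus the added effect on flagged heat-wave
#' days. Counts are negative binomial with variance
#' `overdispersion * mu` (Poisson when overdispersion = 1).
#'
#' @param weather a complete [weather_series()].
#' @param dgp a [true_dgp()].
#' @param seed RNG seed.
#' @param exposure column of `weather` driving the V-shape
#'   (default `"tmean"`).
#' @param hw_indicator optional 0/1 vector of heat-wave days receiving
#'   `hw_added_effect`.
#' @return a [count_series()]; the true log-rate is attached as
#'   attribute `log_mu`.
#' @export
simulate_counts <- function(weather, dgp, seed = 1L, exposure = "tmean",
                            hw_indicator = NULL) {
  stopifnot(inherits(dgp, "true_dgp"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(weather)
  x <- weather[[exposure]]
  cal <- calendar_features(weather)
  v <- vshape(dgp, x)
  lag_term <- numeric(n)
  for (l in 0:3) {
    idx <- (l + 1):n
    lag_term[idx] <- lag_term[idx] + dgp$lag_weights[l + 1] * v[idx - l]
  }
  log_mu <- dgp$baseline_log_rate +
    dgp$trend_per_year * cal$years_elapsed +
    dgp$dow_effects[as.integer(cal$day_of_week)] +
    dgp$holiday_effect * weather$holiday +
    lag_term
  if (!is.null(hw_indicator)) {
    stopifnot(length(hw_indicator) == n)
    log_mu <- log_mu + dgp$hw_added_effect * hw_indicator
  }
  mu <- exp(log_mu)
  counts <- if (dgp$overdispersion == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = mu / (dgp$overdispersion - 1), mu = mu)
  }
  out <- count_series(weather$date, counts)
  attr(out, "log_mu") <- log_mu
  out
}

#' Closed-form true cumulative relative risk of the DGP
#'
#' `exp(v(x) - v(reference))` with `v` the DGP's V-shape; no sampling.
#'
#' @param dgp a [true_dgp()].
#' @param x exposure value(s).
#' @param reference reference exposure (defaults to the vertex).
#' @return true cumulative (lag 0..3) RR.
#' @export
true_cumulative_rr <- function(dgp, x, reference = dgp$vertex) {
  exp(vshape(dgp, x) - vshape(dgp, reference))
}

#' Closed-form true attributable number on a simulated series
#'
#' Backward-perspective AF per day from the DGP's own lag-distributed
#' V-shape, `AF_t = 1 - exp(-sum_l w_l * v(x_{t-l}))`, times the observed
#' counts, summed over days with full lag history. The decomposition
#' restricts contributions to lagged exposures below (cold) or above
#' (heat) the vertex.
#'
#' @inheritParams simulate_counts
#' @param counts the simulated [count_series()].
#' @param component `"total"`, `"cold"` or `"heat"`.
#' @return list with `an` and `af`.
#' @export
true_attributable_number <- function(weather, counts, dgp,
                                     exposure = "tmean",
                                     component = c("total", "cold", "heat")) {
  component <- match.arg(component)
  x <- weather[[exposure]]
  n <- length(x)
  v <- vshape(dgp, x)
  if (component == "cold") v <- v * (x < dgp$vertex)
  if (component == "heat") v <- v * (x > dgp$vertex)
  s <- numeric(n)
  for (l in 0:3) {
    idx <- 4:n
    s[idx] <- s[idx] + dgp$lag_weights[l + 1] * v[idx - l]
  }
  keep <- 4:n
  af <- 1 - exp(-s[keep])
  an <- sum(af * counts$count[keep])
  list(an = an, af = an / sum(counts$count[keep]))
}

#' Named deterministic fixtures
#'
#' Bundled scenarios with known ground truth: `tiny` (60 days, for oracle
#' tests), `standard` (2300 days, V-shaped temperature effect on),
#' `heatwave` (standard plus a 0.1 added log-risk on days where tmean
#' exceeds its 95th percentile for >= 2 consecutive days) and `null`
#' (no temperature effect). Each bundle ships its DGP for recovery
#' assertions.
#'
#' @param name fixture name.
#' @param seed overrides the fixture's fixed seed (for replicate studies).
#' @return list with `weather`, `counts`, `dgp`, `config`, and for
#'   `heatwave` the `hw_indicator` used.
#' @export
generate_fixture <- function(name = c("tiny", "standard", "heatwave",
                                      "null"), seed = NULL) {
  name <- match.arg(name)
  base_seed <- switch(name, tiny = 101L, standard = 2011L,
                      heatwave = 407L, null = 555L)
  seed <- as.integer(seed %||% base_seed)
  n <- if (name == "tiny") 400L else 2300L
  config <- simulation_config(n_days = n, seed = seed)
  weather <- simulate_weather(config)
  if (name == "tiny") {
    weather <- weather_series(
      date = weather$date[1:60], tmin = weather$tmin[1:60],
      tmean = weather$tmean[1:60], tmax = weather$tmax[1:60],
      rh_min = weather$rh_min[1:60], rh_mean = weather$rh_mean[1:60],
      rh_max = weather$rh_max[1:60], wind = weather$wind[1:60],
      precip = weather$precip[1:60], visibility = weather$visibility[1:60],
      holiday = weather$holiday[1:60])
  }
  dgp <- switch(name,
    null = true_dgp(trend_per_year = 0, dow_effects = rep(0, 7),
                    holiday_effect = 0, cold_slope = 0, heat_slope = 0),
    heatwave = true_dgp(hw_added_effect = 0.1),
    true_dgp())
  hw_ind <- NULL
  if (name == "heatwave") {
    def <- heatwave_definition("tmean", "percentile", 95, 2)
    hw_ind <- detect_heatwaves(weather$tmean, def)$indicator
  }
  counts <- simulate_counts(weather, dgp, seed = seed + 1L,
                            hw_indicator = hw_ind)
  out <- list(weather = weather, counts = counts, dgp = dgp,
              config = config)
  if (!is.null(hw_ind)) out$hw_indicator <- hw_ind
  out
}
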