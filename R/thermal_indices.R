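# Unit identity used everywhere vapor pressure changes units.
MMHG_PER_HPA <- 1 / 1.333224

#' Saturation vapor pressure (Magnus form)
#'
#' `es(T) = 6.112 * exp(17.67 * T / (T + 243.5))` hPa over water, accurate to
#' about 0.3 percent over -40..50 deg C. Strictly positive and strictly
#' increasing in `T`.
#'
#' @param T dry-bulb temperature (deg C).
#' @return saturation vapor pressure (hPa = mbar).
#' @export
saturation_vapor_pressure <- function(T) {
  6.112 * exp(17.67 * T / (T + 243.5))
}

#' Vapor pressure from relative humidity
#'
#' `vp = (RH/100) * es(T)` in hPa.
#'
#' @param T dry-bulb temperature (deg C).
#' @param RH relative humidity (percent, in \[0, 100\]).
#' @return vapor pressure (hPa).
#' @export
vapor_pressure_from_rh <- function(T, RH) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE))
    hl_stop("RH outside [0,100]")
  (RH / 100) * saturation_vapor_pressure(T)
}

#' Humidex
#'
#' `Humidex = T + 0.5555 * (vp - 10)` with vapor pressure in hPa (mbar).
#' Equals `T` exactly at vp = 10 hPa.
#'
#' @param T dry-bulb temperature (deg C).
#' @param vp vapor pressure (hPa).
#' @return Humidex (deg C equivalent).
#' @export
humidex <- function(T, vp) {
  if (any(vp < 0, na.rm = TRUE)) hl_stop("vapor pressure must be >= 0")
  T + 0.5555 * (vp - 10)
}

#' Wet-bulb globe temperature (two-variable approximation)
#'
#' The radiation-free approximation from dry-bulb temperature and vapor
#' pressure in mmHg. The default `"additive"` form is
#' `0.567*T + 0.393*vp + 3.94`. The `"literal_product"` form multiplies the
#' three terms (`0.567*T * 0.393*vp * 3.94`); it produces physically
#' implausible values and is retained only for audit.
#'
#' Vapor pressure is accepted in hPa by default and converted internally
#' (1 mmHg = 1.333224 hPa); pass `vp_unit = "mmHg"` to skip conversion.
#'
#' @param T dry-bulb temperature (deg C).
#' @param vp vapor pressure.
#' @param form `"additive"` (default) or `"literal_product"`.
#' @param vp_unit `"hPa"` (default) or `"mmHg"`.
#' @return WBGT index.
#' @export
wbgt <- function(T, vp, form = c("additive", "literal_product"),
                 vp_unit = c("hPa", "mmHg")) {
  form <- match.arg(form)
  vp_unit <- match.arg(vp_unit)
  if (any(vp < 0, na.rm = TRUE)) hl_stop("vapor pressure must be >= 0")
  vp_mmhg <- if (vp_unit == "hPa") vp * MMHG_PER_HPA else vp
  switch(form,
    additive = 0.567 * T + 0.393 * vp_mmhg + 3.94,
    literal_product = 0.567 * T * 0.393 * vp_mmhg * 3.94)
}

#' Auxiliary thermal-stress indices (provisional standard forms)
#'
#' Apparent temperature `AT = T + 0.33*vp - 0.70*v - 4.00` (vp in hPa, wind
#' converted from km/h to m/s); Missenard effective temperature
#' `ET = T - 0.4*(T - 10)*(1 - RH/100)` (equal to `T` at saturation); and
#' the wind-corrected net effective temperature
#' `NET = 37 - (37 - T)/(0.68 - 0.0014*RH + 1/(1.76 + 1.4*v^0.75))
#'        - 0.29*T*(1 - 0.01*RH)`.
#' RH is recovered from `vp` and the saturation curve. These are standard
#' published forms, not formulas taken from any specific study supplement;
#' results carry attribute `provisional = TRUE`.
#'
#' @param T dry-bulb temperature (deg C).
#' @param vp vapor pressure (hPa).
#' @param wind wind velocity (km/h, >= 0).
#' @param which one of `"apparent"`, `"effective"`, `"net_effective"`.
#' @return numeric vector with attribute `provisional = TRUE`.
#' @export
auxiliary_indices <- function(T, vp, wind = 0,
                              which = c("apparent", "effective",
                                        "net_effective")) {
  which <- match.arg(which)
  if (any(wind < 0, na.rm = TRUE)) hl_stop("wind must be >= 0")
  v_ms <- wind / 3.6
  RH <- 100 * vp / saturation_vapor_pressure(T)
  out <- switch(which,
    apparent = T + 0.33 * vp - 0.70 * v_ms - 4.00,
    effective = T - 0.4 * (T - 10) * (1 - RH / 100),
    net_effective = 37 - (37 - T) /
      (0.68 - 0.0014 * RH + 1 / (1.76 + 1.4 * v_ms^0.75)) -
      0.29 * T * (1 - 0.01 * RH))
  attr(out, "provisional") <- TRUE
  out
}

#' Add thermal-stress index columns to a weather series
#'
#' Computes daily Humidex, WBGT (additive form), apparent, effective and net
#' effective temperature from mean temperature, mean relative humidity and
#' wind, plus an apparent temperature driven by `tmax` and `rh_min`
#' (daytime conditions) used by heat-wave definitions.
#'
#' @param weather a [weather_series()] with `tmean`, `rh_mean`, `wind`.
#' @return the weather series with columns `humidex`, `wbgt`, `apparent`,
#'   `effective`, `net_effective`, `apparent_max` appended.
#' @export
add_thermal_indices <- function(weather) {
  need <- c("tmean", "rh_mean")
  miss <- setdiff(need, names(weather))
  if (length(miss)) hl_stop("missing column(s): ", paste(miss, collapse = ", "))
  wind <- if ("wind" %in% names(weather)) weather$wind else 0
  vp <- vapor_pressure_from_rh(weather$tmean, weather$rh_mean)
  weather$humidex <- humidex(weather$tmean, vp)
  weather$wbgt <- wbgt(weather$tmean, vp)
  weather$apparent <- as.numeric(auxiliary_indices(weather$tmean, vp, wind,
                                                   "apparent"))
  weather$effective <- as.numeric(auxiliary_indices(weather$tmean, vp, wind,
                                                    "effective"))
  weather$net_effective <- as.numeric(auxiliary_indices(weather$tmean, vp,
                                                        wind, "net_effective"))
  if (all(c("tmax", "rh_min") %in% names(weather))) {
    vpx <- vapor_pressure_from_rh(weather$tmax, weather$rh_min)
    weather$apparent_max <- as.numeric(auxiliary_indices(weather$tmax, vpx,
                                                         wind, "apparent"))
  }
  weather
}
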