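#' Heat-wave definition
#'
#' A heat wave is a run of at least `min_duration` consecutive days on
#' which a temperature metric strictly exceeds a threshold, given either
#' as a percentile of the study series itself or as an absolute value in
#' degrees Celsius.
#'
#' @param metric one of `"tmin"`, `"tmean"`, `"tmax"`, `"apparent"`
#'   (daytime apparent temperature, computed from `tmax`).
#' @param threshold_kind `"percentile"` or `"absolute"`.
#' @param threshold_value percentile in (0, 100) or degrees Celsius.
#' @param min_duration minimum run length in days (>= 1).
#' @param id unique label.
#' @return object of class `heatwave_definition`.
#' @export
heatwave_definition <- function(metric, threshold_kind, threshold_value,
                                min_duration, id = NULL) {
  metric <- match.arg(metric, c("tmin", "tmean", "tmax", "apparent"))
  threshold_kind <- match.arg(threshold_kind, c("percentile", "absolute"))
  stopifnot(min_duration >= 1)
  if (threshold_kind == "percentile" &&
      (threshold_value <= 0 || threshold_value >= 100))
    hl_stop("percentile threshold must be in (0, 100)")
  if (is.null(id))
    id <- paste0(metric, "_",
                 if (threshold_kind == "percentile")
                   paste0("p", threshold_value)
                 else paste0("abs", threshold_value),
                 "_d", min_duration)
  structure(list(metric = metric, threshold_kind = threshold_kind,
                 threshold_value = threshold_value,
                 min_duration = as.integer(min_duration), id = id),
            class = "heatwave_definition")
}

#' The sixteen-definition heat-wave catalog
#'
#' Kent-style grid: metrics tmin/tmean/tmax/apparent crossed with
#' thresholds >90th, >95th, >99th percentile (duration >= 2 days) and
#' absolute > 35 degrees C (duration >= 1 day). Shipped as a JSON config
#' (`inst/extdata/heatwave_catalog.json`) so an alternative list can be
#' substituted.
#'
#' @param path catalog file; default the bundled one.
#' @return list of sixteen [heatwave_definition()]s with unique ids.
#' @export
heatwave_catalog <- function(path = system.file("extdata",
                                                "heatwave_catalog.json",
                                                package = "heatlag")) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  defs <- lapply(seq_len(nrow(raw)), function(i)
    heatwave_definition(raw$metric[i], raw$threshold_kind[i],
                        raw$threshold_value[i], raw$min_duration[i],
                        raw$id[i]))
  ids <- vapply(defs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) hl_stop("catalog ids are not unique")
  defs
}

#' Detect heat-wave days
#'
#' Flags every day belonging to a run of at least `min_duration`
#' consecutive days on which the metric strictly exceeds the threshold
#' (all days of a qualifying run are flagged; shorter runs contribute
#' none).
#'
#' @param x numeric metric series (complete over the study window).
#' @param definition a [heatwave_definition()].
#' @return list with `indicator` (0/1 vector), `days` (flagged-day
#'   count), `threshold` (resolved threshold value).
#' @export
detect_heatwaves <- function(x, definition) {
  stopifnot(inherits(definition, "heatwave_definition"))
  thr <- if (definition$threshold_kind == "percentile") {
    if (max(x) - min(x) < 1e-12)
      hl_stop("percentile threshold undefined on a constant series")
    hl_quantile(x, definition$threshold_value / 100)
  } else definition$threshold_value
  hot <- x > thr
  r <- rle(hot)
  keep <- r$values & r$lengths >= definition$min_duration
  ind <- as.integer(inverse.rle(list(values = keep, lengths = r$lengths)))
  list(indicator = ind, days = sum(ind), threshold = unname(thr))
}

# Metric series for a definition; apparent uses daytime conditions.
heatwave_metric <- function(weather, metric) {
  if (metric == "apparent") {
    if (!"apparent_max" %in% names(weather))
      weather <- add_thermal_indices(weather)
    if ("apparent_max" %in% names(weather)) return(weather$apparent_max)
    return(weather$apparent)
  }
  if (!metric %in% names(weather)) hl_stop("metric '", metric, "' absent")
  weather[[metric]]
}

#' Added heat-wave effect on top of the smooth temperature term
#'
#' Refits the main DLNM with the heat-wave indicator entered as
#' unconstrained lag strata 0..L (one indicator column per lag) and
#' reports the added relative risk on heat-wave days at lag 0 and
#' cumulated over lags 0..L, with delta-method 95 percent CIs.
#'
#' @inheritParams build_design
#' @param definition a [heatwave_definition()].
#' @return data frame rows `lag0` and `lag0L`: `rr`, `ci_low`, `ci_high`;
#'   attributes `days` and `id`.
#' @export
added_effect_model <- function(weather, counts, spec = model_spec(),
                               definition) {
  det <- detect_heatwaves(heatwave_metric(weather, definition$metric),
                          definition)
  if (det$days == 0)
    hl_stop("definition '", definition$id, "' yields no heat-wave days")
  des <- build_design(weather, counts, spec)
  L <- des$crossbasis$max_lag
  n <- nrow(weather)
  hw <- matrix(0, n, L + 1)
  for (l in 0:L)
    hw[(l + 1):n, l + 1] <- det$indicator[seq_len(n - l)]
  colnames(hw) <- paste0("hw_lag", 0:L)
  X <- cbind(des$X, hw[des$rows, , drop = FALSE])
  labels <- des$labels
  labels$heatwave <- ncol(des$X) + seq_len(L + 1)
  fit <- fit_quasipoisson(des$y, X, labels)
  idx <- labels$heatwave
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  z <- stats::qnorm(0.975)
  se0 <- sqrt(V[1, 1])
  secum <- sqrt(sum(V))
  out <- data.frame(
    lag = c("lag0", paste0("lag0", L)),
    rr = exp(c(b[1], sum(b))),
    ci_low = exp(c(b[1] - z * se0, sum(b) - z * secum)),
    ci_high = exp(c(b[1] + z * se0, sum(b) + z * secum)))
  attr(out, "days") <- det$days
  attr(out, "id") <- definition$id
  attr(out, "fit") <- fit
  out
}

#' Heat-wave table across a catalog
#'
#' Day counts and added-effect RRs for every definition in a catalog;
#' definitions yielding zero heat-wave days are reported with `NA` risks.
#'
#' @inheritParams added_effect_model
#' @param catalog list of [heatwave_definition()]s.
#' @return data frame, one row per definition: `id`, `metric`,
#'   `threshold`, `days`, `rr_lag0`, `rr_lag0_low`, `rr_lag0_high`,
#'   `rr_lag0L`, `rr_lag0L_low`, `rr_lag0L_high`.
#' @export
heatwave_table <- function(weather, counts, spec = model_spec(),
                           catalog = heatwave_catalog()) {
  rows <- lapply(catalog, function(def) {
    det <- detect_heatwaves(heatwave_metric(weather, def$metric), def)
    base <- data.frame(id = def$id, metric = def$metric,
                       threshold = det$threshold, days = det$days)
    if (det$days == 0) {
      hl_log(paste0("definition '", def$id, "' yields no heat-wave days"))
      return(cbind(base, rr_lag0 = NA_real_, rr_lag0_low = NA_real_,
                   rr_lag0_high = NA_real_, rr_lag0L = NA_real_,
                   rr_lag0L_low = NA_real_, rr_lag0L_high = NA_real_))
    }
    ae <- added_effect_model(weather, counts, spec, def)
    cbind(base, rr_lag0 = ae$rr[1], rr_lag0_low = ae$ci_low[1],
          rr_lag0_high = ae$ci_high[1], rr_lag0L = ae$rr[2],
          rr_lag0L_low = ae$ci_low[2], rr_lag0L_high = ae$ci_high[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
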