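#' Construct and validate a daily weather series
#'
#' A `weather_series` is a data frame of contiguous daily meteorological
#' observations: temperatures in degrees Celsius, relative humidity in
#' percent, wind velocity in km/h, precipitation in mm/day, an optional
#' 5-level ordinal visibility code (0 = normal .. 4 = visibility < 200 m)
#' and a binary holiday indicator. Validation enforces strictly increasing
#' dates with a step of exactly one day, `tmin <= tmean <= tmax` rowwise,
#' humidity within \[0, 100\] and non-negative wind and precipitation.
#' Missing values in optional fields are permitted and flagged; modelling
#' stages drop flagged rows (and rows whose lag window touches one).
#'
#' @param date `Date` vector, one entry per day.
#' @param tmin,tmean,tmax daily minimum / mean / maximum temperature (deg C).
#' @param rh_min,rh_mean,rh_max relative humidity (percent), optional.
#' @param wind daily wind velocity (km/h), optional.
#' @param precip daily precipitation (mm/day), optional.
#' @param visibility ordinal dust-visibility code in `0:4`, optional.
#' @param holiday binary holiday indicator (0/1), defaults to all 0.
#' @return A data frame of class `weather_series`.
#' @export
weather_series <- function(date, tmin = NULL, tmean = NULL, tmax = NULL,
                           rh_min = NULL, rh_mean = NULL, rh_max = NULL,
                           wind = NULL, precip = NULL, visibility = NULL,
                           holiday = NULL) {
  date <- as.Date(date)
  n <- length(date)
  cols <- list(date = date)
  opt <- list(tmin = tmin, tmean = tmean, tmax = tmax,
              rh_min = rh_min, rh_mean = rh_mean, rh_max = rh_max,
              wind = wind, precip = precip, visibility = visibility)
  for (nm in names(opt)) {
    v <- opt[[nm]]
    if (!is.null(v)) {
      if (length(v) != n) hl_stop("column '", nm, "' has length ", length(v),
                                  ", expected ", n)
      cols[[nm]] <- as.numeric(v)
    }
  }
  cols$holiday <- if (is.null(holiday)) integer(n) else as.integer(holiday)
  x <- structure(as.data.frame(cols, stringsAsFactors = FALSE),
                 class = c("weather_series", "data.frame"))
  validate_weather_series(x)
}

#' @rdname weather_series
#' @param x object to validate.
#' @export
validate_weather_series <- function(x) {
  stopifnot(is.data.frame(x), "date" %in% names(x))
  d <- as.Date(x$date)
  if (anyDuplicated(d)) {
    dup <- d[duplicated(d)][1]
    hl_stop("duplicated date: ", format(dup))
  }
  if (length(d) > 1) {
    step <- diff(as.integer(d))
    if (any(step <= 0)) hl_stop("dates are not strictly increasing at row ",
                                which(step <= 0)[1] + 1L)
    if (any(step != 1)) hl_stop("date gap before ",
                                format(d[which(step != 1)[1] + 1L]),
                                "; daily series must be contiguous")
  }
  if (all(c("tmin", "tmean", "tmax") %in% names(x))) {
    bad <- which(x$tmin > x$tmean | x$tmean > x$tmax)
    if (length(bad))
      hl_stop("temperature ordering tmin <= tmean <= tmax violated at row ",
              bad[1], " (date ", format(d[bad[1]]), ")")
  }
  for (nm in intersect(c("rh_min", "rh_mean", "rh_max"), names(x))) {
    bad <- which(x[[nm]] < 0 | x[[nm]] > 100)
    if (length(bad)) hl_stop("'", nm, "' outside [0,100] at row ", bad[1])
  }
  for (nm in intersect(c("wind", "precip"), names(x))) {
    bad <- which(x[[nm]] < 0)
    if (length(bad)) hl_stop("'", nm, "' negative at row ", bad[1])
  }
  if ("visibility" %in% names(x)) {
    v <- x$visibility[!is.na(x$visibility)]
    if (length(v) && !all(v %in% 0:4))
      hl_stop("'visibility' must be an ordinal code in 0..4")
  }
  x
}

#' Construct a daily count series
#'
#' Daily medical-attendance counts aligned one-to-one with a
#' [weather_series()] after joining on date.
#'
#' @param date `Date` vector.
#' @param count non-negative integer daily counts.
#' @return A data frame of class `count_series`.
#' @export
count_series <- function(date, count) {
  date <- as.Date(date)
  if (anyDuplicated(date))
    hl_stop("duplicated date: ", format(date[duplicated(date)][1]))
  if (any(is.na(count))) hl_stop("counts contain missing values")
  if (any(count < 0) || any(count != round(count)))
    hl_stop("counts must be non-negative integers (row ",
            which(count < 0 | count != round(count))[1], ")")
  structure(data.frame(date = date, count = as.integer(round(count))),
            class = c("count_series", "data.frame"))
}

#' Read a daily weather/count series from a delimited text file
#'
#' Reads a CSV with one row per day and ISO-8601 dates, maps columns to the
#' canonical field names via `column_map`, validates the result and returns
#' the weather and count sides separately. Missing optional columns yield
#' absent fields, not failures.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`date`, `count`, `tmin`, `tmean`, `tmax`, `rh_min`, `rh_mean`,
#'   `rh_max`, `wind`, `precip`, `visibility`, `holiday`) to the file's
#'   column names. Defaults to the identity mapping.
#' @param sep field separator, default `","`.
#' @return `list(weather = <weather_series>, counts = <count_series>)`.
#' @export
read_daily_series <- function(path, column_map = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("date", "count", "tmin", "tmean", "tmax", "rh_min",
                 "rh_mean", "rh_max", "wind", "precip", "visibility",
                 "holiday")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  for (req in c("date", "count"))
    if (!map[[req]] %in% names(raw))
      hl_stop("mandatory column '", map[[req]], "' (", req,
              ") missing from ", path)
  get <- function(nm) if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else NULL
  d <- as.Date(get("date"), format = "%Y-%m-%d")
  if (any(is.na(d)))
    hl_stop("unparseable date at row ", which(is.na(d))[1], ": '",
            get("date")[which(is.na(d))[1]], "'")
  ord <- order(d)
  d <- d[ord]
  w <- weather_series(date = d,
                      tmin = get("tmin")[ord], tmean = get("tmean")[ord],
                      tmax = get("tmax")[ord],
                      rh_min = get("rh_min")[ord], rh_mean = get("rh_mean")[ord],
                      rh_max = get("rh_max")[ord],
                      wind = get("wind")[ord], precip = get("precip")[ord],
                      visibility = get("visibility")[ord],
                      holiday = get("holiday")[ord])
  list(weather = w, counts = count_series(d, get("count")[ord]))
}

#' Write a weather/count series to CSV
#'
#' Full-precision writer; a write/read round trip reproduces every finite
#' field bit-exactly.
#'
#' @param weather a [weather_series()].
#' @param counts a [count_series()] aligned with `weather`, or `NULL`.
#' @param path output file path.
#' @export
write_daily_series <- function(weather, counts = NULL, path) {
  out <- as.data.frame(weather)
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  if (!is.null(counts)) {
    stopifnot(all(as.Date(counts$date) == as.Date(weather$date)))
    out$count <- counts$count
  }
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calendar features for model adjustment
#'
#' Derives the day-of-week factor (7 civil-calendar levels, Monday first),
#' the holiday indicator from an explicit holiday date list, a 0-based time
#' index and fractional years elapsed. No weekend convention is hard-coded:
#' holiday semantics come solely from the supplied list.
#'
#' @param series a [weather_series()] (or anything with a `date` column).
#' @param holidays `Date` vector of holidays; dates outside the series range
#'   are ignored with a logged warning.
#' @return data frame with `date`, `day_of_week`, `holiday`, `time_index`,
#'   `years_elapsed`.
#' @export
calendar_features <- function(series, holidays = as.Date(character())) {
  d <- as.Date(series$date)
  holidays <- as.Date(holidays)
  outside <- holidays[holidays < min(d) | holidays > max(d)]
  if (length(outside))
    hl_log(paste0(length(outside), " holiday date(s) outside series range ignored"))
  dow <- factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
    as.integer(format(d, "%u"))],
    levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  ti <- as.integer(d - d[1])
  data.frame(date = d,
             day_of_week = dow,
             holiday = as.integer(d %in% holidays),
             time_index = ti,
             years_elapsed = ti / 365.25)
}

#' Descriptive summary table (mean and SD by calendar group)
#'
#' Per-group mean and sample standard deviation (n-1 denominator) of the
#' daily count and every meteorological field present, in the layout of a
#' standard "Table 1" (mean +/- SD by year, month, day of week or holiday).
#'
#' @param weather a [weather_series()].
#' @param counts a [count_series()] aligned with `weather`.
#' @param group_by one of `"year"`, `"month"`, `"day_of_week"`, `"holiday"`.
#' @return data frame: one row per non-empty group; columns `group`, `n`,
#'   then `<field>_mean` / `<field>_sd` for `count` and each weather field.
#' @export
descriptive_summary <- function(weather, counts,
                                group_by = c("year", "month", "day_of_week",
                                             "holiday")) {
  group_by <- match.arg(group_by)
  d <- as.Date(weather$date)
  stopifnot(all(as.Date(counts$date) == d))
  g <- switch(group_by,
    year = factor(format(d, "%Y")),
    month = factor(months(d, abbreviate = TRUE), levels = month.abb),
    day_of_week = calendar_features(weather)$day_of_week,
    holiday = factor(ifelse(weather$holiday == 1, "Yes", "No"),
                     levels = c("No", "Yes")))
  fields <- c(list(count = counts$count),
              as.list(weather[setdiff(names(weather), c("date", "holiday"))]))
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty))
    hl_log(paste0("empty group(s) omitted: ", paste(empty, collapse = ", ")))
  keep <- levels(g)[levels(g) %in% as.character(g)]
  out <- data.frame(group = keep,
                    n = as.integer(table(g)[keep]),
                    stringsAsFactors = FALSE)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    out[[paste0(nm, "_mean")]] <- vapply(keep, function(k)
      mean(v[g == k], na.rm = TRUE), numeric(1))
    out[[paste0(nm, "_sd")]] <- vapply(keep, function(k)
      stats::sd(v[g == k], na.rm = TRUE), numeric(1))
  }
  rownames(out) <- NULL
  out
}
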