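write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("reading a daily CSV returns validated, date-sorted series", {
  f <- write_csv_lines(c(
    "date,count,tmin,tmean,tmax",
    "2011-03-23,11,3,9,16",
    "2011-03-21,10,2,8,15",
    "2011-03-22,12,1,7,14"))
  ds <- read_daily_series(f)
  expect_s3_class(ds$weather, "weather_series")
  expect_s3_class(ds$counts, "count_series")
  expect_equal(nrow(ds$counts), 3)
  expect_equal(ds$counts$count, c(10L, 12L, 11L))
  expect_equal(ds$weather$tmean, c(8, 7, 9))
})

test_that("invalid inputs are rejected naming the offending column or row", {
  dup <- write_csv_lines(c("date,count", "2011-03-21,10", "2011-03-21,11"))
  expect_error(read_daily_series(dup), "2011-03-21")
  badt <- write_csv_lines(c(
    "date,count,tmin,tmean,tmax",
    "2011-03-21,10,1,3,8",
    "2011-03-22,10,5,4,2"))
  expect_error(read_daily_series(badt), "row 2")
  gap <- write_csv_lines(c("date,count", "2011-03-21,10", "2011-03-23,11"))
  expect_error(read_daily_series(gap), "gap")
  nod <- write_csv_lines(c("day,count", "2011-03-21,10"))
  expect_error(read_daily_series(nod), "date")
  badd <- write_csv_lines(c("date,count", "2011-03-21,10", "not-a-date,11"))
  expect_error(read_daily_series(badd), "unparseable")
  expect_error(count_series(as.Date("2011-03-21"), -1), "non-negative")
})

test_that("column_map renames file columns to canonical fields", {
  f <- write_csv_lines(c("DATUM,N,T", "2011-03-21,4,12.5", "2011-03-22,6,13"))
  ds <- read_daily_series(f, column_map = c(date = "DATUM", count = "N",
                                            tmean = "T"))
  expect_equal(ds$counts$count, c(4L, 6L))
  expect_equal(ds$weather$tmean, c(12.5, 13))
  expect_false("tmin" %in% names(ds$weather))
})

test_that("calendar features follow the civil calendar and holiday list", {
  # 2011-03-21 is a Monday
  w <- weather_series(date = seq(as.Date("2011-03-21"), by = 1, length.out = 7),
                      tmean = rep(10, 7))
  cal <- calendar_features(w)
  expect_equal(as.character(cal$day_of_week),
               c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  expect_equal(cal$holiday, rep(0L, 7))
  expect_equal(cal$time_index, 0:6)
  cal2 <- calendar_features(w, holidays = as.Date("2011-03-23"))
  expect_equal(cal2$holiday, c(0L, 0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("years_elapsed uses day counts over 365.25", {
  w <- weather_series(date = seq(as.Date("2011-01-01"), by = 1,
                                 length.out = 730))
  cal <- calendar_features(w)
  expect_equal(cal$years_elapsed[730], 729 / 365.25, tolerance = 1e-12)
})

test_that("descriptive summary reports group means and sample SDs", {
  d <- seq(as.Date("2012-01-10"), by = 1, length.out = 2)
  w <- weather_series(date = d, tmean = c(4, 6))
  cnt <- count_series(d, c(10, 20))
  s <- descriptive_summary(w, cnt, "month")
  expect_equal(nrow(s), 1)
  expect_equal(s$group, "Jan")
  expect_equal(s$count_mean, 15.0)
  expect_equal(s$count_sd, sqrt(50), tolerance = 1e-12)

  d2 <- seq(as.Date("2011-03-21"), by = 1, length.out = 14)
  w2 <- weather_series(date = d2, tmean = rep(10, 14))
  cnt2 <- count_series(d2, rep(5, 14))
  s2 <- descriptive_summary(w2, cnt2, "day_of_week")
  expect_equal(nrow(s2), 7)
  expect_equal(s2$n, rep(2L, 7))
  expect_equal(s2$count_mean, rep(5, 7))
  expect_equal(s2$count_sd, rep(0, 7))
})

test_that("group sizes sum to the series length for any partition", {
  fx <- generate_fixture("tiny")
  for (g in c("year", "month", "day_of_week", "holiday")) {
    s <- descriptive_summary(fx$weather, fx$counts, g)
    expect_equal(sum(s$n), nrow(fx$weather))
  }
})

test_that("write then read round-trips all fields bit-exactly", {
  fx <- generate_fixture("tiny")
  f <- tempfile(fileext = ".csv")
  write_daily_series(fx$weather, fx$counts, f)
  ds <- read_daily_series(f)
  for (nm in setdiff(names(fx$weather), c("date", "holiday")))
    expect_identical(ds$weather[[nm]], as.numeric(fx$weather[[nm]]))
  expect_identical(ds$weather$holiday, fx$weather$holiday)
  expect_identical(ds$counts$count, fx$counts$count)
  expect_identical(as.Date(ds$weather$date), as.Date(fx$weather$date))
})
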