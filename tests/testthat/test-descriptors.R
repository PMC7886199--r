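test_that("daily summaries reduce constant and sinusoidal days correctly", {
  days <- seq(as.Date("2016-07-01"), as.Date("2016-07-03"), by = "day")
  flat <- make_hourly_series(days, function(ts, hod) rep(10, length(ts)))
  d <- daily_summaries(flat)
  expect_equal(nrow(d), 3L)
  expect_equal(d$tmax, rep(10, 3))
  expect_equal(d$tmin, rep(10, 3))
  expect_equal(d$trange, rep(0, 3))
  expect_equal(d$tvar, rep(0, 3))
  expect_true(all(d$qualifying))

  sine <- make_hourly_series(days, function(ts, hod)
    10 + 2 * sin(2 * pi * hod / 24))
  ds <- daily_summaries(sine)
  hod_vals <- 10 + 2 * sin(2 * pi * (0:23) / 24)
  expect_equal(ds$trange[1], max(hod_vals) - min(hod_vals), tolerance = 1e-12)
  expect_equal(ds$tvar[1], var(hod_vals), tolerance = 1e-12)
  expect_true(ds$tmin[1] <= ds$tmean[1] && ds$tmean[1] <= ds$tmax[1])
})

test_that("incomplete days are flagged by the completeness threshold", {
  days <- as.Date("2016-07-01")
  s <- make_hourly_series(days, function(ts, hod) rep(12, length(ts)))
  s$timestamp <- s$timestamp[1:20]
  s$temp_c <- s$temp_c[1:20]
  d <- daily_summaries(s, min_completeness = 0.9)
  expect_false(d$qualifying) # 20/24 < 0.9
  expect_equal(d$n_hours, 20L)
})

test_that("water-year seasons follow the Oct-Sep partition", {
  x <- assign_season(as.Date(c("2016-07-15", "2015-10-01", "2016-03-31",
                               "2016-09-30", "2016-10-01")))
  expect_equal(x$water_year, c(2016L, 2016L, 2016L, 2016L, 2017L))
  expect_equal(as.character(x$season),
               c("Summer", "Fall", "Winter", "Summer", "Fall"))
  # the four windows partition the water year
  wy <- assign_season(seq(as.Date("2015-10-01"), as.Date("2016-09-30"),
                          by = "day"))
  expect_true(all(wy$water_year == 2016L))
  expect_equal(as.integer(table(wy$season)[c("Fall", "Winter", "Spring",
                                             "Summer")]),
               c(92L, 91L, 91L, 92L))
})

test_that("MWMT handles constant and single-spike series by arithmetic", {
  win <- season_window(2016, "Summer")
  dates <- seq(win$start, win$end, by = "day")
  n <- length(dates)
  daily <- data.frame(date = dates, qualifying = TRUE,
                      tmax = rep(15, n), tmean = rep(14, n),
                      tmin = 13, trange = 2, tvar = 0.1)
  expect_equal(unname(weekly_max_statistics(daily, 2016, "Summer")["mwmt"]),
               15)
  daily$tmax <- rep(10, n)
  daily$tmax[40] <- 17
  expect_equal(unname(weekly_max_statistics(daily, 2016, "Summer")["mwmt"]),
               (6 * 10 + 17) / 7)
})

test_that("weekly statistics match the exhaustive window-scan oracle", {
  for (seed in 1:25) {
    daily <- random_season_daily(seed)
    got <- weekly_max_statistics(daily, 2016, "Summer")
    expect_equal(unname(got["mwmt"]),
                 oracle_weekly_max(daily$date, daily$tmax, daily$qualifying))
    expect_equal(unname(got["mwat"]),
                 oracle_weekly_max(daily$date, daily$tmean, daily$qualifying))
  }
})

test_that("degree days equal naive summation and toy arithmetic", {
  win <- season_window(2016, "Summer")
  daily <- data.frame(date = win$start + 0:2, qualifying = TRUE,
                      tmax = 15, tmean = c(10, 12, 14), tmin = 8,
                      trange = 7, tvar = 0.2)
  expect_equal(degree_days(daily, 2016, "Summer"), 36)
  daily$tmean <- 0
  expect_equal(degree_days(daily, 2016, "Summer"), 0)
  for (seed in 1:10) {
    d <- random_season_daily(seed + 100)
    expect_equal(degree_days(d, 2016, "Summer"),
                 oracle_degree_days(d$tmean, d$qualifying))
  }
})

test_that("threshold exceedance counts days and longest runs", {
  win <- season_window(2016, "Summer")
  daily <- data.frame(date = win$start + 0:4, qualifying = TRUE,
                      tmax = c(15, 17, 18, 15, 17), tmean = 14, tmin = 10,
                      trange = 5, tvar = 1)
  got <- threshold_exceedance(daily, 2016, "Summer", 16)
  expect_equal(unname(got), c(3L, 2L))
  daily$tmax <- rep(10, 5)
  expect_equal(unname(threshold_exceedance(daily, 2016, "Summer", 16)),
               c(0L, 0L))
})

test_that("exceedance matches the run-length oracle on random seasons", {
  for (seed in 1:25) {
    daily <- random_season_daily(seed + 200, p_present = 0.85)
    got <- threshold_exceedance(daily, 2016, "Summer", 16)
    win <- season_window(2016, "Summer")
    grid <- seq(win$start, win$end, by = "day")
    idx <- match(grid, daily$date)
    above <- !is.na(idx) & daily$qualifying[ifelse(is.na(idx), 1L, idx)] &
      daily$tmax[ifelse(is.na(idx), 1L, idx)] > 16
    expect_equal(unname(got["days_above"]), sum(above))
    expect_equal(unname(got["max_consecutive"]), oracle_longest_run(above))
  }
})

test_that("the descriptor vector is consistent with its parts", {
  days <- seq(as.Date("2016-07-01"), as.Date("2016-09-30"), by = "day")
  s <- make_hourly_series(days, function(ts, hod)
    14 + 3 * cos(2 * pi * (hod - 15) / 24))
  set.seed(9)
  s$temp_c <- s$temp_c + rnorm(length(s$temp_c), 0, 0.3)
  daily <- daily_summaries(s)
  rd <- regime_descriptors(daily, 2016, "Summer")
  wk <- weekly_max_statistics(daily, 2016, "Summer")
  expect_equal(rd$mwmt, unname(wk["mwmt"]))
  expect_equal(rd$mwat, unname(wk["mwat"]))
  expect_equal(rd$degree_days, degree_days(daily, 2016, "Summer"))
  ex <- threshold_exceedance(daily, 2016, "Summer", 16)
  expect_equal(rd$days_gt_16, unname(ex["days_above"]))
  expect_equal(rd$avg_daily_max, mean(daily$tmax))
  expect_true(rd$mwat <= rd$mwmt)
  expect_true(rd$avg_daily_min <= rd$avg_daily_mean)
  expect_true(rd$avg_daily_mean <= rd$avg_daily_max)
  expect_false(rd$low_coverage)
})

test_that("constant seasons give degenerate descriptors", {
  days <- seq(as.Date("2016-07-01"), as.Date("2016-09-30"), by = "day")
  s <- make_hourly_series(days, function(ts, hod) rep(10, length(ts)))
  rd <- regime_descriptors(daily_summaries(s), 2016, "Summer")
  expect_equal(rd$avg_daily_max, 10)
  expect_equal(rd$mwmt, 10)
  expect_equal(rd$avg_daily_min, 10)
  expect_equal(rd$degree_days, 10 * 92)
  expect_equal(rd$avg_daily_range, 0)
  expect_equal(rd$max_variance, 0)
  expect_equal(rd$days_gt_16, 0L)
  expect_equal(rd$max_consec_gt_20, 0L)
})

test_that("magnitude descriptors shift by +c; variability is unchanged", {
  days <- seq(as.Date("2016-07-01"), as.Date("2016-09-30"), by = "day")
  set.seed(11)
  base <- make_hourly_series(days, function(ts, hod)
    12 + 2 * cos(2 * pi * (hod - 15) / 24))
  base$temp_c <- base$temp_c + rnorm(length(base$temp_c), 0, 0.5)
  r0 <- regime_descriptors(daily_summaries(base), 2016, "Summer")
  shifted <- base
  shifted$temp_c <- base$temp_c + 1.5
  r1 <- regime_descriptors(daily_summaries(shifted), 2016, "Summer")
  for (m in c("avg_daily_max", "mwmt", "avg_daily_mean", "mwat",
              "avg_daily_min"))
    expect_equal(r1[[m]], r0[[m]] + 1.5, tolerance = 1e-10)
  expect_equal(r1$degree_days, r0$degree_days + 1.5 * r0$n_days,
               tolerance = 1e-10)
  for (m in c("avg_daily_range", "max_daily_range", "avg_variance",
              "max_variance"))
    expect_equal(r1[[m]], r0[[m]], tolerance = 1e-10)
})

test_that("descriptors are invariant to input row order", {
  days <- seq(as.Date("2016-07-01"), as.Date("2016-07-31"), by = "day")
  set.seed(3)
  s <- make_hourly_series(days, function(ts, hod) 15 + runif(length(ts)))
  perm <- sample(length(s$timestamp))
  shuffled <- list(timestamp = s$timestamp[perm], temp_c = s$temp_c[perm])
  expect_equal(daily_summaries(shuffled), daily_summaries(s))
})

test_that("a mid-season excluded day breaks MWMT windows", {
  win <- season_window(2016, "Summer")
  dates <- seq(win$start, win$end, by = "day")
  n <- length(dates)
  daily <- data.frame(date = dates, qualifying = TRUE,
                      tmax = rep(10, n), tmean = 9, tmin = 8, trange = 2,
                      tvar = 0.1)
  daily$tmax[30:36] <- 20 # a hot week
  daily$qualifying[33] <- FALSE # excluded day inside it
  got <- weekly_max_statistics(daily, 2016, "Summer")
  expect_lt(unname(got["mwmt"]), 20)
  expect_equal(unname(got["mwmt"]),
               oracle_weekly_max(daily$date, daily$tmax, daily$qualifying))
})
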