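# Independent brute-force oracles used to verify the descriptor and
# multivariate computations. These deliberately share no code with the
# package implementations.

# exhaustive scan over every 7-consecutive-calendar-day window
oracle_weekly_max <- function(dates, vals, ok) {
  best <- NA_real_
  for (i in seq_along(dates)) {
    win <- dates[i] + 0:6
    idx <- match(win, dates)
    if (anyNA(idx)) next
    if (!all(ok[idx])) next
    m <- mean(vals[idx])
    if (is.na(best) || m > best) best <- m
  }
  best
}

# longest run of TRUE by explicit scan
oracle_longest_run <- function(above) {
  best <- 0L; cur <- 0L
  for (a in above) {
    if (isTRUE(a)) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else cur <- 0L
  }
  best
}

# naive summation of daily means over qualifying days
oracle_degree_days <- function(tmean, ok) {
  total <- 0
  for (i in seq_along(tmean)) if (ok[i]) total <- total + tmean[i]
  total
}

# Kruskal stress-1 of a configuration against dissimilarities d, using
# least-squares monotone regression (isoreg) of configuration distances on
# the dissimilarity order
oracle_stress1 <- function(d, conf) {
  dh <- as.numeric(stats::dist(conf))
  d <- as.numeric(d)
  o <- order(d)
  iso <- stats::isoreg(seq_along(o), dh[o])
  dhat <- numeric(length(dh))
  dhat[o] <- iso$yf
  sqrt(sum((dh - dhat)^2) / sum(dh^2))
}

# one-factor PerMANOVA pseudo-F from squared Euclidean distances, computed
# directly from the distance matrix partition
oracle_pseudo_f <- function(x, groups) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# random daily-summary table for one season of a water year, with random
# missing and non-qualifying days
random_season_daily <- function(seed, water_year = 2016, season = "Summer",
                                p_present = 0.9, p_qualify = 0.95) {
  set.seed(seed)
  win <- season_window(water_year, season)
  dates <- seq(win$start, win$end, by = "day")
  keep <- stats::runif(length(dates)) < p_present
  dates <- dates[keep]
  n <- length(dates)
  tmax <- stats::runif(n, 8, 22)
  tmean <- tmax - stats::runif(n, 0.5, 3)
  tmin <- tmean - stats::runif(n, 0.5, 3)
  data.frame(date = dates, n_hours = 24L, completeness = 1,
             qualifying = stats::runif(n) < p_qualify,
             tmax = tmax, tmin = tmin, tmean = tmean,
             trange = tmax - tmin,
             tvar = stats::runif(n, 0, 2))
}

# hourly series for a list of days: 24 values per day from a given function
make_hourly_series <- function(dates, temp_fun) {
  ts <- as.POSIXct(outer(0:23 * 3600,
                         as.numeric(as.POSIXct(paste(dates, "00:00:00"),
                                               tz = "UTC")), `+`),
                   origin = "1970-01-01", tz = "UTC")
  ts <- sort(ts)
  hod <- as.integer(format(ts, "%H"))
  list(timestamp = ts, temp_c = temp_fun(ts, hod))
}
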