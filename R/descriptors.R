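#' Daily summaries of an hourly temperature series
#'
#' Collapses hourly water temperatures to one row per calendar day with the
#' daily maximum, minimum, mean, range, and within-day variance (sample
#' variance of the day's hourly values). Days with fewer than
#' \code{min_completeness} of 24 hours present are flagged incomplete and are
#' excluded from seasonal statistics downstream (but retained here).
#'
#' @param series data frame with columns \code{timestamp} (POSIXct or
#'   ISO 8601 character, local standard time) and \code{temp_c}.
#' @param min_completeness minimum fraction of the 24 hourly values a day must
#'   have to qualify (default 0.9).
#' @return data frame with columns \code{date}, \code{n_hours},
#'   \code{completeness}, \code{qualifying}, \code{tmax}, \code{tmin},
#'   \code{tmean}, \code{trange}, \code{tvar}.
#' @export
daily_summaries <- function(series, min_completeness = 0.9) {
  if (NROW(series) == 0L) stop("empty series")
  ts <- series$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC")
  if (any(is.na(ts))) stop("malformed timestamps in series")
  x <- series$temp_c
  dayn <- floor(as.numeric(ts) / 86400) # UTC day number, fast grouping key
  keep <- is.finite(x)
  dayn <- dayn[keep]; x <- x[keep]
  if (!length(x)) stop("no finite temperatures in series")

  ud <- sort(unique(dayn))
  f <- structure(match(dayn, ud), levels = as.character(ud),
                 class = "factor")
  st <- vapply(split(x, f), function(v) {
    n <- length(v)
    m <- sum(v) / n
    c(n, max(v), min(v), m,
      if (n > 1L) sum((v - m)^2) / (n - 1L) else 0)
  }, numeric(5L))
  out <- data.frame(
    date = as.Date(ud, origin = "1970-01-01"),
    n_hours = as.integer(st[1L, ]),
    completeness = st[1L, ] / 24,
    tmax = st[2L, ],
    tmin = st[3L, ],
    tmean = st[4L, ],
    tvar = st[5L, ],
    row.names = NULL
  )
  out$trange <- out$tmax - out$tmin
  out$qualifying <- out$completeness >= min_completeness
  out[, c("date", "n_hours", "completeness", "qualifying",
          "tmax", "tmin", "tmean", "trange", "tvar")]
}

#' Assign water year and season to dates
#'
#' The water year runs Oct 1 through Sep 30 and is labelled by the ending
#' calendar year. Seasons partition the water year: Fall (Oct 1 - Dec 31),
#' Winter (Jan 1 - Mar 31), Spring (Apr 1 - Jun 30), Summer (Jul 1 - Sep 30).
#'
#' @param dates a Date vector (or coercible).
#' @return data frame with columns \code{date}, \code{water_year} (integer),
#'   \code{season} (factor Fall/Winter/Spring/Summer).
#' @export
#' @examples
#' assign_season(as.Date(c("2015-10-01", "2016-03-31", "2016-07-15")))
assign_season <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  mo <- lt$mon + 1L
  yr <- lt$year + 1900L
  wy <- ifelse(mo >= 10L, yr + 1L, yr)
  season <- c("Winter", "Winter", "Winter", "Spring", "Spring", "Spring",
              "Summer", "Summer", "Summer", "Fall", "Fall", "Fall")[mo]
  data.frame(date = dates, water_year = wy,
             season = factor(season, levels = season_levels()))
}

season_levels <- function() c("Fall", "Winter", "Spring", "Summer")

#' Season date window within a water year
#'
#' @param water_year integer water-year label (ends Sep 30 of that year).
#' @param season one of "Fall", "Winter", "Spring", "Summer".
#' @return list with \code{start} and \code{end} Dates (inclusive).
#' @export
season_window <- function(water_year, season) {
  season <- match.arg(season, season_levels())
  switch(season,
    Fall   = list(start = as.Date(sprintf("%d-10-01", water_year - 1L)),
                  end   = as.Date(sprintf("%d-12-31", water_year - 1L))),
    Winter = list(start = as.Date(sprintf("%d-01-01", water_year)),
                  end   = as.Date(sprintf("%d-03-31", water_year))),
    Spring = list(start = as.Date(sprintf("%d-04-01", water_year)),
                  end   = as.Date(sprintf("%d-06-30", water_year))),
    Summer = list(start = as.Date(sprintf("%d-07-01", water_year)),
                  end   = as.Date(sprintf("%d-09-30", water_year)))
  )
}

# Expand a season's daily table onto its full calendar grid. Returns a list
# with aligned vectors over every calendar day of the season; absent or
# non-qualifying days carry NA values and ok = FALSE.
season_grid <- function(daily, water_year, season) {
  win <- season_window(water_year, season)
  grid <- seq(win$start, win$end, by = "day")
  idx <- match(grid, daily$date)
  ok <- !is.na(idx) & daily$qualifying[pmax(idx, 1L)]
  ok[is.na(ok)] <- FALSE
  pick <- function(col) {
    v <- rep(NA_real_, length(grid))
    v[ok] <- daily[[col]][idx[ok]]
    v
  }
  list(dates = grid, ok = ok,
       tmax = pick("tmax"), tmin = pick("tmin"), tmean = pick("tmean"),
       trange = pick("trange"), tvar = pick("tvar"))
}

#' Maximum weekly statistics (MWMT, MWAT)
#'
#' MWMT is the maximum, over all 7-consecutive-calendar-day windows lying
#' fully inside the season, of the mean of daily maximum temperatures; MWAT is
#' the same statistic on daily means. Windows containing an absent or
#' non-qualifying day are skipped. Returns \code{NA} when no window qualifies.
#'
#' @param daily daily summary table from [daily_summaries()].
#' @param water_year integer water-year label.
#' @param season season name.
#' @return named numeric vector \code{c(mwmt =, mwat =)}.
#' @export
weekly_max_statistics <- function(daily, water_year, season) {
  g <- season_grid(daily, water_year, season)
  c(mwmt = rolling7_max(g$tmax, g$ok),
    mwat = rolling7_max(g$tmean, g$ok))
}

# max over 7-day windows of the window mean; windows with any !ok day skipped
rolling7_max <- function(x, ok) {
  n <- length(x)
  if (n < 7L) return(NA_real_)
  x0 <- ifelse(ok, x, 0)
  csum <- cumsum(c(0, x0))
  cok <- cumsum(c(0L, as.integer(ok)))
  starts <- seq_len(n - 6L)
  full <- (cok[starts + 7L] - cok[starts]) == 7L
  if (!any(full)) return(NA_real_)
  means <- (csum[starts + 7L] - csum[starts]) / 7
  max(means[full])
}

#' Cumulative seasonal degree days
#'
#' Sum of daily mean temperatures over qualifying days in the season window
#' (base 0 degrees C).
#'
#' @inheritParams weekly_max_statistics
#' @return degree days (degrees C times days); \code{NA} if no qualifying day.
#' @export
degree_days <- function(daily, water_year, season) {
  g <- season_grid(daily, water_year, season)
  if (!any(g$ok)) return(NA_real_)
  sum(g$tmean[g$ok])
}

#' Threshold exceedance frequency and duration
#'
#' Counts days whose daily maximum exceeds a threshold, and the length of the
#' longest run of consecutive calendar days all exceeding it. A day absent
#' from the record (or non-qualifying) breaks a run. The daily statistic is
#' configurable (regulatory cold-water criteria are conventionally applied to
#' daily maxima).
#'
#' @inheritParams weekly_max_statistics
#' @param threshold temperature threshold in degrees C (e.g. 16 or 20).
#' @param statistic daily statistic compared to the threshold: "tmax"
#'   (default) or "tmean".
#' @return named numeric vector \code{c(days_above =, max_consecutive =)}.
#' @export
threshold_exceedance <- function(daily, water_year, season, threshold,
                                 statistic = c("tmax", "tmean")) {
  statistic <- match.arg(statistic)
  g <- season_grid(daily, water_year, season)
  v <- g[[statistic]]
  above <- g$ok & !is.na(v) & v > threshold
  days_above <- sum(above)
  max_consec <- 0L
  if (days_above > 0L) {
    r <- rle(above)
    max_consec <- max(r$lengths[r$values])
  }
  c(days_above = as.integer(days_above),
    max_consecutive = as.integer(max_consec))
}

#' Names of the standard thermal-regime descriptors
#'
#' The default 14-descriptor suite: six magnitude descriptors (average daily
#' maximum, MWMT, average daily mean, MWAT, degree days, average daily
#' minimum), four variability descriptors (average and maximum daily range,
#' average and maximum within-day variance), and four frequency/duration
#' descriptors (days and maximum consecutive days above 16 and 20 degrees C).
#'
#' @return character vector of descriptor names.
#' @export
descriptor_names <- function() {
  c("avg_daily_max", "mwmt", "avg_daily_mean", "mwat", "degree_days",
    "avg_daily_min", "avg_daily_range", "max_daily_range",
    "avg_variance", "max_variance",
    "days_gt_16", "max_consec_gt_16", "days_gt_20", "max_consec_gt_20")
}

#' Thermal-regime descriptors for one season
#'
#' Computes the full descriptor suite from a daily summary table for a given
#' water year and season. Magnitude and variability descriptors are means or
#' maxima over qualifying days; MWMT/MWAT come from
#' [weekly_max_statistics()]; exceedance descriptors from
#' [threshold_exceedance()]. The season is flagged low coverage when fewer
#' than \code{min_coverage} of its calendar days qualify.
#'
#' @inheritParams weekly_max_statistics
#' @param thresholds numeric thresholds (degrees C) for exceedance
#'   descriptors; default \code{c(16, 20)}.
#' @param min_coverage minimum fraction of season days that must qualify for
#'   the season to count as well covered (default 0.8).
#' @return one-row data frame with the descriptors of [descriptor_names()]
#'   plus \code{n_days}, \code{coverage} and \code{low_coverage}.
#' @export
regime_descriptors <- function(daily, water_year, season,
                               thresholds = c(16, 20), min_coverage = 0.8) {
  g <- season_grid(daily, water_year, season)
  ok <- g$ok
  coverage <- mean(ok)
  wk <- weekly_max_statistics(daily, water_year, season)
  m <- function(v) if (any(ok)) mean(v[ok]) else NA_real_
  mx <- function(v) if (any(ok)) max(v[ok]) else NA_real_
  ex <- lapply(thresholds, function(th)
    threshold_exceedance(daily, water_year, season, th))
  out <- data.frame(
    water_year = water_year, season = season,
    avg_daily_max = m(g$tmax),
    mwmt = unname(wk["mwmt"]),
    avg_daily_mean = m(g$tmean),
    mwat = unname(wk["mwat"]),
    degree_days = degree_days(daily, water_year, season),
    avg_daily_min = m(g$tmin),
    avg_daily_range = m(g$trange),
    max_daily_range = mx(g$trange),
    avg_variance = m(g$tvar),
    max_variance = mx(g$tvar),
    n_days = sum(ok), coverage = coverage,
    low_coverage = coverage < min_coverage
  )
  for (i in seq_along(thresholds)) {
    th <- round(thresholds[i])
    out[[sprintf("days_gt_%d", th)]] <- as.integer(ex[[i]][["days_above"]])
    out[[sprintf("max_consec_gt_%d", th)]] <- as.integer(ex[[i]][["max_consecutive"]])
  }
  rownames(out) <- NULL
  out
}

#' Descriptor table for a multi-sensor study
#'
#' Runs the full hourly-to-descriptor pipeline for every sensor in a logger
#' table and returns one row per (site, reach-or-sensor, water year, season).
#' At \code{level = "reach"} the reach is represented by the sensor at its
#' downstream extent (\code{reach_bottom}), integrating thermal exposure over
#' the reach; \code{level = "sensor"} keeps every sensor (needed for
#' longitudinal profiles).
#'
#' @param temps hourly logger table with columns \code{site}, \code{reach},
#'   \code{position}, \code{distance_m}, \code{timestamp}, \code{temp_c}
#'   (see [read_hourly_temps()]).
#' @param level "reach" (default) or "sensor".
#' @param min_completeness forwarded to [daily_summaries()].
#' @param thresholds forwarded to [regime_descriptors()].
#' @param seasons optional subset of seasons to compute (default all four).
#' @return data frame of descriptors keyed by \code{site}, \code{reach},
#'   \code{position}, \code{distance_m}, \code{water_year}, \code{season}.
#' @export
descriptor_table <- function(temps, level = c("reach", "sensor"),
                             min_completeness = 0.9, thresholds = c(16, 20),
                             seasons = NULL) {
  level <- match.arg(level)
  if (level == "reach")
    temps <- temps[temps$position == "reach_bottom", , drop = FALSE]
  if (nrow(temps) == 0L) stop("no sensor rows to summarize")
  key <- interaction(temps$site, temps$reach, temps$position, drop = TRUE)
  res <- lapply(split(seq_len(nrow(temps)), key), function(i) {
    d <- temps[i, c("site", "reach", "position", "distance_m"), drop = FALSE]
    daily <- daily_summaries(
      list(timestamp = temps$timestamp[i], temp_c = temps$temp_c[i]),
      min_completeness = min_completeness)
    ss <- assign_season(daily$date)
    combos <- unique(data.frame(water_year = ss$water_year,
                                season = as.character(ss$season)))
    if (!is.null(seasons))
      combos <- combos[combos$season %in% seasons, , drop = FALSE]
    if (!nrow(combos)) return(NULL)
    rows <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      regime_descriptors(daily, combos$water_year[i], combos$season[i],
                         thresholds = thresholds)))
    cbind(site = d$site[1L], reach = d$reach[1L], position = d$position[1L],
          distance_m = d$distance_m[1L], rows)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no rows for the requested seasons")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$site, out$distance_m, out$water_year,
            match(out$season, season_levels())), , drop = FALSE]
}
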