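# Readers and writers for the tabular formats the pipeline consumes. All
# downstream modules work from these validated data frames, never raw files.
# CSV dialect: comma-separated, UTF-8, "." decimal; timestamps ISO 8601 local
# standard time (field loggers run on a fixed clock offset, no DST).

TEMP_BOUNDS <- c(-1, 40) # plausibility bounds (deg C) for QA flagging

#' Read an hourly water-temperature logger table
#'
#' Expects a CSV with header columns \code{site}, \code{reach},
#' \code{position}, \code{distance_m}, \code{timestamp}, \code{temp_c}.
#' Timestamps must parse as ISO 8601 and be unique and strictly increasing
#' within each sensor. Gaps in the hourly grid are recorded (attribute
#' \code{"gaps"}), and temperatures outside the plausibility bounds
#' \[-1, 40\] degrees C are flagged in a QA column (\code{suspect}), not
#' silently dropped: suspect rows are excluded from daily summaries by being
#' set to \code{NA} in \code{temp_c} while the raw value is kept in
#' \code{temp_c_raw}.
#'
#' @param path path to the CSV file.
#' @return data frame of hourly records with attributes \code{"gaps"} (data
#'   frame of per-sensor gap intervals) and \code{"n_suspect"}.
#' @export
read_hourly_temps <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "reach", "position", "distance_m", "timestamp", "temp_c")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("hourly temperature file missing columns: ",
         paste(miss, collapse = ", "))
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt)) # ISO 8601 "T" separator
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC"))
  if (any(is.na(ts)))
    stop("malformed timestamp(s), e.g. '",
         raw$timestamp[which(is.na(ts))[1L]], "'")
  raw$timestamp <- ts
  validate_hourly_temps(raw)
}

#' Validate an in-memory hourly temperature table
#'
#' Applies the same QA as [read_hourly_temps()]: duplicate (sensor,
#' timestamp) rows are an error, gaps are recorded, out-of-bounds values are
#' flagged and masked.
#'
#' @param temps data frame with logger-table columns (POSIXct timestamps).
#' @return validated data frame with QA attributes.
#' @export
validate_hourly_temps <- function(temps) {
  key <- interaction(temps$site, temps$reach, temps$position, drop = TRUE)
  gaps <- list(); n_suspect <- 0L
  parts <- split(seq_len(nrow(temps)), key)
  for (nm in names(parts)) {
    i <- parts[[nm]]
    tt <- temps$timestamp[i]
    o <- order(tt)
    i <- i[o]; tt <- tt[o]
    dup <- duplicated(tt)
    if (any(dup))
      stop("duplicate timestamp for sensor ", nm, " at ",
           format(tt[dup][1L], "%Y-%m-%d %H:%M:%S"))
    dh <- as.numeric(difftime(tt[-1L], tt[-length(tt)], units = "hours"))
    jump <- which(dh > 1)
    if (length(jump))
      gaps[[nm]] <- data.frame(sensor = nm,
                               gap_start = tt[jump], gap_end = tt[jump + 1L],
                               hours_missing = dh[jump] - 1)
  }
  ord <- order(temps$site, temps$distance_m, temps$timestamp)
  temps <- temps[ord, , drop = FALSE]
  suspect <- !is.na(temps$temp_c) &
    (temps$temp_c < TEMP_BOUNDS[1L] | temps$temp_c > TEMP_BOUNDS[2L])
  temps$temp_c_raw <- temps$temp_c
  temps$suspect <- suspect
  temps$temp_c[suspect] <- NA_real_
  rownames(temps) <- NULL
  attr(temps, "gaps") <- if (length(gaps)) do.call(rbind, c(gaps, make.row.names = FALSE))
                         else data.frame(sensor = character(), gap_start = as.POSIXct(character()),
                                         gap_end = as.POSIXct(character()), hours_missing = numeric())
  attr(temps, "n_suspect") <- sum(suspect)
  temps
}

#' Write an hourly temperature table to CSV
#'
#' Inverse of [read_hourly_temps()] for the canonical columns;
#' \code{read(write(x))} round-trips bit-identically.
#'
#' @param temps validated hourly table.
#' @param path output path.
#' @export
write_hourly_temps <- function(temps, path) {
  out <- temps[, c("site", "reach", "position", "distance_m",
                   "timestamp", "temp_c")]
  out$temp_c <- ifelse(is.na(out$temp_c) & !is.na(temps$temp_c_raw),
                       temps$temp_c_raw, out$temp_c)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site covariate table
#'
#' Physical site characteristics of the experimental reaches: watershed
#' position (distance upstream, m), reach length (m), bankfull width (m),
#' aspect (deg), gradient (%), elevation (m), plus optional covariates
#' (proximity to upstream treatment, air and upstream temperature summaries).
#'
#' @param path path to a CSV; defaults to the packaged table of the ten
#'   study reaches.
#' @return validated data frame, one row per site.
#' @export
read_site_covariates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "site_covariates.csv",
                        package = "streamtherm", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("watershed", "site", "distance_upstream_m", "reach_length_m",
            "bankfull_width_m", "aspect_deg", "gradient_pct", "elevation_m")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("site covariate file missing columns: ", paste(miss, collapse = ", "))
  if (any(x$gradient_pct < 0)) stop("gradient must be non-negative")
  if (any(x$aspect_deg < 0 | x$aspect_deg >= 360))
    stop("aspect must lie in [0, 360)")
  x
}

#' Read hemispherical-photo shade records
#'
#' One row per photograph: \code{site}, \code{reach}, \code{year},
#' \code{photo}, \code{vis_sky} (open-sky fraction), \code{gsf} (global site
#' factor), both fractions in \[0, 1\].
#'
#' @param path path to a CSV.
#' @return validated data frame; an empty file yields an empty collection
#'   with a warning.
#' @export
read_shade_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "reach", "year", "photo", "vis_sky", "gsf")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("shade record file missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) {
    warning("shade record file is empty: ", path)
    return(x)
  }
  check_fraction(x$vis_sky, "vis_sky")
  check_fraction(x$gsf, "gsf")
  x
}

#' Read paired pyranometer light records
#'
#' One row per instrument-hour: \code{site}, \code{reach}, \code{year},
#' \code{pyranometer}, \code{hour}, \code{below}, \code{above} (W m-2).
#'
#' @param path path to a CSV.
#' @return validated data frame.
#' @export
read_light_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "reach", "year", "pyranometer", "hour", "below", "above")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("light record file missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) {
    warning("light record file is empty: ", path)
    return(x)
  }
  if (any(x$below < 0) || any(x$above < 0))
    stop("irradiance must be non-negative")
  x
}
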