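#' Canopy closure from hemispherical-photo open-sky fraction
#'
#' Canopy closure is the percentage of the full hemispherical view occluded by
#' canopy: \code{(1 - VisSky) * 100}, where VisSky is the fraction of photo
#' pixels open to the sky.
#'
#' @param vis_sky numeric vector of open-sky fractions in \[0, 1\].
#' @return numeric vector of canopy closure percentages in \[0, 100\].
#' @seealso [effective_shade()], [percent_transmission()]
#' @export
#' @examples
#' canopy_closure(c(0, 0.063, 1))
canopy_closure <- function(vis_sky) {
  check_fraction(vis_sky, "vis_sky")
  (1 - vis_sky) * 100
}

#' Effective shade from the global site factor
#'
#' Effective shade is the percentage of the solar path occluded by canopy:
#' \code{(1 - GSF) * 100}, where GSF (global site factor) is the open fraction
#' of pixels along the sun's track.
#'
#' @param gsf numeric vector of global site factors in \[0, 1\].
#' @return numeric vector of effective shade percentages in \[0, 100\].
#' @export
#' @examples
#' effective_shade(c(0, 0.25, 0.5))
effective_shade <- function(gsf) {
  check_fraction(gsf, "gsf")
  (1 - gsf) * 100
}

#' Percent light transmission through the canopy
#'
#' Below-canopy solar radiation reaching the stream expressed as a percentage
#' of the above-canopy radiation available, aggregated as the ratio of daily
#' totals (not a mean of hourly ratios, which is unstable near dawn and dusk
#' when above-canopy irradiance approaches zero).
#'
#' @param below numeric vector, below-canopy irradiance (W m-2), one value per
#'   hour of the paired record.
#' @param above numeric vector, above-canopy irradiance (W m-2), same length.
#' @return percent transmission (scalar).
#' @export
#' @examples
#' percent_transmission(rep(30, 24), rep(500, 24))
percent_transmission <- function(below, above) {
  if (length(below) != length(above))
    stop("'below' and 'above' must be paired records of equal length")
  if (any(!is.finite(below)) || any(!is.finite(above)))
    stop("irradiance records must be finite")
  if (any(below < 0) || any(above < 0))
    stop("irradiance must be non-negative")
  tot_above <- sum(above)
  if (tot_above <= 0)
    stop("above-canopy daily total must be positive")
  100 * sum(below) / tot_above
}

#' Summarize shade and light records to reach-year means
#'
#' Computes per-(site, reach, year) means and SDs of canopy closure, effective
#' shade, and percent transmission from raw photo and pyranometer records. The
#' reach summary is the unweighted mean over photos/pyranometers (sampling is
#' evenly spaced along the reach).
#'
#' @param shade data frame of photo records with columns \code{site},
#'   \code{reach}, \code{year}, \code{photo}, \code{vis_sky}, \code{gsf}.
#' @param light data frame of pyranometer records with columns \code{site},
#'   \code{reach}, \code{year}, \code{pyranometer}, \code{hour}, \code{below},
#'   \code{above}. May be \code{NULL} to summarize shade only.
#' @return data frame with one row per (site, reach, year): mean and SD of
#'   canopy closure (%), effective shade (%), percent transmission (%), and the
#'   numbers of photos and pyranometers. SDs are \code{NA} for single records.
#' @export
summarize_shade_light <- function(shade, light = NULL) {
  need <- c("site", "reach", "year", "vis_sky", "gsf")
  if (!all(need %in% names(shade)))
    stop("shade records need columns: ", paste(need, collapse = ", "))
  if (nrow(shade) == 0L) stop("no shade records to summarize")
  check_fraction(shade$vis_sky, "vis_sky")
  check_fraction(shade$gsf, "gsf")

  key <- interaction(shade$site, shade$reach, shade$year, drop = TRUE)
  cc <- canopy_closure(shade$vis_sky)
  es <- effective_shade(shade$gsf)
  out <- data.frame(
    site  = tapply(as.character(shade$site), key, `[`, 1L),
    reach = tapply(as.character(shade$reach), key, `[`, 1L),
    year  = tapply(shade$year, key, `[`, 1L),
    n_photos = as.integer(tapply(cc, key, length)),
    canopy_closure = as.numeric(tapply(cc, key, mean)),
    canopy_closure_sd = as.numeric(tapply(cc, key, stats::sd)),
    effective_shade = as.numeric(tapply(es, key, mean)),
    effective_shade_sd = as.numeric(tapply(es, key, stats::sd)),
    row.names = NULL
  )

  if (!is.null(light) && nrow(light) > 0L) {
    lkey <- interaction(light$site, light$reach, light$year, light$pyranometer,
                        drop = TRUE)
    trans <- vapply(split(light, lkey), function(d)
      percent_transmission(d$below, d$above), numeric(1))
    meta <- do.call(rbind, lapply(split(light, lkey), function(d)
      d[1L, c("site", "reach", "year")]))
    tkey <- interaction(meta$site, meta$reach, meta$year, drop = TRUE)
    tr <- data.frame(
      site  = tapply(as.character(meta$site), tkey, `[`, 1L),
      reach = tapply(as.character(meta$reach), tkey, `[`, 1L),
      year  = tapply(meta$year, tkey, `[`, 1L),
      n_pyranometers = as.integer(tapply(trans, tkey, length)),
      transmission = as.numeric(tapply(trans, tkey, mean)),
      transmission_sd = as.numeric(tapply(trans, tkey, stats::sd)),
      row.names = NULL
    )
    out <- merge(out, tr, by = c("site", "reach", "year"), all = TRUE)
  } else {
    out$n_pyranometers <- NA_integer_
    out$transmission <- NA_real_
    out$transmission_sd <- NA_real_
  }
  out[order(out$site, out$reach, out$year), , drop = FALSE]
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'", name, "' must lie in [0, 1]")
  invisible(x)
}
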