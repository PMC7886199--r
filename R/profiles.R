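# Longitudinal profiles: how far a local temperature increase carries
# downstream, visualized as the pre-to-post change in a descriptor at each
# sensor, anchored to zero at the upstream end of the upstream reference
# reach so sites are comparable.

#' Build a zero-anchored longitudinal profile
#'
#' For one site and season, takes the sensor-level descriptor table (see
#' [descriptor_table()] with \code{level = "sensor"}), computes the
#' post-minus-pre change of the chosen descriptor at every sensor ordered by
#' channel distance, and subtracts the change at the upstream-most sensor so
#' the profile starts at exactly zero.
#'
#' @param descriptors sensor-level descriptor table with columns \code{site},
#'   \code{reach}, \code{position}, \code{distance_m}, \code{water_year},
#'   \code{season} and the descriptor columns.
#' @param site site id to profile.
#' @param season season name.
#' @param pre_year,post_year water-year labels of the two years compared.
#' @param descriptor descriptor column to profile (default \code{"mwmt"}).
#' @return object of class \code{longitudinal_profile}: data frame with
#'   \code{distance_m}, \code{reach}, \code{delta} (raw change) and
#'   \code{anchored} (change minus the upstream-most change; first value 0).
#' @export
longitudinal_profile <- function(descriptors, site, season,
                                 pre_year, post_year, descriptor = "mwmt") {
  if (!descriptor %in% names(descriptors))
    stop("unknown descriptor: ", descriptor)
  d <- descriptors[descriptors$site == site &
                     descriptors$season == season, , drop = FALSE]
  pre <- d[d$water_year == pre_year, , drop = FALSE]
  post <- d[d$water_year == post_year, , drop = FALSE]
  m <- merge(pre[, c("distance_m", "reach", "position", descriptor)],
             post[, c("distance_m", descriptor)],
             by = "distance_m", suffixes = c("_pre", "_post"))
  m <- m[order(m$distance_m), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need the descriptor pre and post at >= 2 sensors for site ", site)
  delta <- m[[paste0(descriptor, "_post")]] - m[[paste0(descriptor, "_pre")]]
  if (any(!is.finite(delta)))
    stop("descriptor unavailable pre or post at some sensor for site ", site)
  if (!(m$reach[1L] == "upstream" && m$position[1L] == "reach_top"))
    stop("anchor (upstream-most) sensor missing for site ", site)
  out <- data.frame(site = site, season = season,
                    distance_m = m$distance_m, reach = m$reach,
                    delta = delta, anchored = delta - delta[1L])
  attr(out, "descriptor") <- descriptor
  class(out) <- c("longitudinal_profile", "data.frame")
  out
}

#' Classify the downstream trajectory of an anchored profile
#'
#' Quantifies the qualitative downstream patterns: \code{"undetectable"} when
#' no anchored change exceeds \code{tol} in magnitude; \code{"persists"} when
#' the value at the downstream extent is still at least half of the peak
#' change; \code{"dissipates"} otherwise (the local increase decayed before
#' the downstream extent).
#'
#' @param profile a [longitudinal_profile()] (or any numeric vector of
#'   anchored changes).
#' @param tol detectability threshold in degrees C (default 0.2).
#' @param persist_fraction fraction of the peak change that must remain at the
#'   final sensor to call the effect persistent (default 0.5).
#' @return one of \code{"persists"}, \code{"dissipates"},
#'   \code{"undetectable"}.
#' @export
classify_trajectory <- function(profile, tol = 0.2, persist_fraction = 0.5) {
  z <- if (is.data.frame(profile)) profile$anchored else as.numeric(profile)
  if (length(z) < 3L) stop("need a profile with at least 3 points")
  if (max(abs(z)) <= tol) return("undetectable")
  peak <- max(z)
  if (z[length(z)] >= persist_fraction * peak) "persists" else "dissipates"
}

#' @export
print.longitudinal_profile <- function(x, ...) {
  cat("Longitudinal profile of", attr(x, "descriptor"), "change, site",
      x$site[1L], "-", as.character(x$season[1L]), "\n")
  print(as.data.frame(x)[, c("distance_m", "reach", "delta", "anchored")])
  invisible(x)
}

#' Plot a longitudinal profile
#'
#' Anchored change against channel distance with the thinned reach shaded.
#'
#' @param x a [longitudinal_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.longitudinal_profile <- function(x, ...) {
  graphics::plot(x$distance_m, x$anchored, type = "n",
                 xlab = "Distance along channel (m)",
                 ylab = "Anchored change (deg C)",
                 main = paste("Site", x$site[1L], "-", x$season[1L]), ...)
  th <- which(x$reach == "thinned")
  if (length(th)) {
    x0 <- if (min(th) > 1L) x$distance_m[min(th) - 1L] else x$distance_m[min(th)]
    graphics::rect(x0, graphics::par("usr")[3L],
                   max(x$distance_m[th]), graphics::par("usr")[4L],
                   col = grDevices::adjustcolor("goldenrod", 0.25),
                   border = NA)
  }
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::lines(x$distance_m, x$anchored, type = "b", pch = 16)
  invisible(x)
}
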