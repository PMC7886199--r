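#' Configuration for a synthetic BACI thinning study
#'
#' Bundles and validates every knob of the synthetic-study generator. The
#' defaults describe the study conditions the pipeline is validated against: a
#' replicated three-reach (upstream reference / thinned / downstream) design
#' at 10 sites in three watersheds, hourly water temperatures over one
#' pre-treatment and one post-treatment water year, a post-treatment
#' perturbation concentrated on daylight hours in the thinned reach (so daily
#' maxima, range and variance respond while daily minima do not), roughly half
#' of the thinned-reach response persisting to the downstream reach boundary,
#' near-closed pre-treatment canopies (~95 % closure, ~6 % light
#' transmission), and thinning-scale shade losses and light gains.
#'
#' @param seed integer random seed; the same config yields bit-identical data.
#' @param n_sites number of replicated sites (default 10).
#' @param watershed_labels watershed per site; recycled if shorter than
#'   \code{n_sites}.
#' @param reach_lengths_m lengths (m) of the upstream, thinned and downstream
#'   reaches.
#' @param pre_year,post_year water-year labels of the pre- and post-treatment
#'   years (must differ).
#' @param baseline_annual_mean_C annual mean water temperature (deg C).
#' @param annual_amplitude_C half peak-to-trough seasonal swing (deg C).
#' @param diel_amplitude_summer_C deterministic summer daily range (deg C);
#'   the diel cycle shrinks toward winter.
#' @param ar1_coef hourly AR(1) coefficient of the site-shared noise, in
#'   \[0, 1).
#' @param noise_sd_C innovation SD (deg C) of the AR(1) noise.
#' @param sensor_noise_sd_C SD of additional sensor-specific white noise.
#' @param site_sd_C between-site SD of baseline temperature (deg C).
#' @param effect_dmax_C injected post-treatment increase of thinned-reach
#'   summer daily maxima (deg C).
#' @param effect_site_sd_C between-site SD of the realized treatment effect.
#' @param effect_downstream_fraction fraction of the thinned-reach
#'   perturbation persisting at the downstream reach boundary, in \[0, 1\].
#' @param effect_season_weights named weights scaling the injected effect by
#'   season (summer 1 by construction; spring/fall partial; winter none).
#' @param shade_loss_closure_pct,shade_loss_effective_pct percentage-point
#'   post-treatment reductions of thinned-reach canopy closure and effective
#'   shade.
#' @param light_gain_pct percentage-point post-treatment increase of
#'   thinned-reach light transmission.
#' @param pre_closure_mean_pct,pre_effective_shade_pct,pre_transmission_pct
#'   pre-treatment reach means (percent).
#' @param shade_kappa concentration of the beta-like noise around reach mean
#'   photo fractions (larger = tighter).
#' @param truncate_pre_to_spring_summer drop pre-treatment fall and winter
#'   records (emulates sensors deployed in spring of the pre-treatment year),
#'   exercising the pipeline's missing-season handling.
#' @return object of class \code{synth_config} (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_sites = 10L,
                         watershed_labels = NULL,
                         reach_lengths_m = c(upstream = 150, thinned = 200,
                                             downstream = 175),
                         pre_year = 2016L,
                         post_year = 2018L,
                         baseline_annual_mean_C = 10.5,
                         annual_amplitude_C = 3.5,
                         diel_amplitude_summer_C = 1.5,
                         ar1_coef = 0.7,
                         noise_sd_C = 0.3,
                         sensor_noise_sd_C = 0.05,
                         site_sd_C = 1.0,
                         effect_dmax_C = 2.8,
                         effect_site_sd_C = 1.0,
                         effect_downstream_fraction = 0.5,
                         effect_season_weights = c(Fall = 0.35, Winter = 0,
                                                   Spring = 0.6, Summer = 1),
                         shade_loss_closure_pct = 17,
                         shade_loss_effective_pct = 23,
                         light_gain_pct = 27,
                         pre_closure_mean_pct = 95,
                         pre_effective_shade_pct = 93,
                         pre_transmission_pct = 6,
                         shade_kappa = 150,
                         truncate_pre_to_spring_summer = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("need at least 2 sites")
  if (is.null(watershed_labels)) {
    watershed_labels <- if (n_sites == 10L)
      rep(c("WFT", "EFT", "LM"), c(5L, 3L, 2L))
    else rep_len(c("WFT", "EFT", "LM"), n_sites)
  }
  watershed_labels <- rep_len(as.character(watershed_labels), n_sites)
  if (identical(pre_year, post_year) || post_year <= pre_year)
    stop("post_year must be a later water year than pre_year")
  num <- c(baseline_annual_mean_C, annual_amplitude_C, diel_amplitude_summer_C,
           ar1_coef, noise_sd_C, sensor_noise_sd_C, site_sd_C, effect_dmax_C,
           effect_site_sd_C, effect_downstream_fraction, shade_kappa)
  if (any(!is.finite(num))) stop("non-finite generator parameter")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must lie in [0, 1)")
  if (effect_downstream_fraction < 0 || effect_downstream_fraction > 1)
    stop("effect_downstream_fraction must lie in [0, 1]")
  pct <- c(shade_loss_closure_pct, shade_loss_effective_pct, light_gain_pct,
           pre_closure_mean_pct, pre_effective_shade_pct, pre_transmission_pct)
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("percentages must lie in [0, 100]")
  w <- effect_season_weights[season_levels()]
  if (any(is.na(w))) stop("effect_season_weights needs all four seasons")
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              watershed_labels = watershed_labels,
              reach_lengths_m = reach_lengths_m,
              pre_year = as.integer(pre_year),
              post_year = as.integer(post_year),
              baseline_annual_mean_C = baseline_annual_mean_C,
              annual_amplitude_C = annual_amplitude_C,
              diel_amplitude_summer_C = diel_amplitude_summer_C,
              ar1_coef = ar1_coef, noise_sd_C = noise_sd_C,
              sensor_noise_sd_C = sensor_noise_sd_C, site_sd_C = site_sd_C,
              effect_dmax_C = effect_dmax_C,
              effect_site_sd_C = effect_site_sd_C,
              effect_downstream_fraction = effect_downstream_fraction,
              effect_season_weights = w,
              shade_loss_closure_pct = shade_loss_closure_pct,
              shade_loss_effective_pct = shade_loss_effective_pct,
              light_gain_pct = light_gain_pct,
              pre_closure_mean_pct = pre_closure_mean_pct,
              pre_effective_shade_pct = pre_effective_shade_pct,
              pre_transmission_pct = pre_transmission_pct,
              shade_kappa = shade_kappa,
              truncate_pre_to_spring_summer =
                isTRUE(truncate_pre_to_spring_summer))
  class(cfg) <- "synth_config"
  cfg
}

# hourly grid of one water year (Oct 1 of wy-1 .. Sep 30 23:00 of wy)
water_year_hours <- function(wy) {
  seq(as.POSIXct(sprintf("%d-10-01 00:00:00", wy - 1L), tz = "UTC"),
      as.POSIXct(sprintf("%d-09-30 23:00:00", wy), tz = "UTC"),
      by = "hour")
}

# deterministic components evaluated on an hourly grid
synth_deterministic <- function(hours, config) {
  doy <- as.integer(format(hours, "%j"))
  hod <- as.integer(format(hours, "%H"))
  seas <- cos(2 * pi * (doy - 228) / 365.25)       # peaks mid-August
  annual <- config$baseline_annual_mean_C + config$annual_amplitude_C * seas
  dielmod <- 0.2 + 0.8 * (1 + seas) / 2            # diel cycle damped in winter
  diel <- (config$diel_amplitude_summer_C / 2) * dielmod *
    cos(2 * pi * (hod - 15) / 24)                  # peaks 15:00, trough 03:00
  # daylight trapezoid perturbation: unit plateau 11:00-19:00 (covering the
  # hours where the daily maximum can fall once noise is added) with short
  # shoulders, zero at night. The plateau makes the realized increase in the
  # daily maximum equal the injected amplitude in expectation; a peaked shape
  # would systematically under-deliver whenever noise shifts the argmax.
  shape <- ifelse(hod >= 10 & hod <= 20, 1,
                  ifelse(hod == 9 | hod == 21, 0.5, 0))
  w <- config$effect_season_weights[as.character(assign_season(
    as.Date(hours, tz = "UTC"))$season)]
  list(annual = annual, diel = diel, effect_shape = shape * as.numeric(w))
}

#' Generate hourly water temperatures for a synthetic BACI study
#'
#' Simulates every sensor of every site over the pre- and post-treatment
#' water years: an annual sinusoid (peaking mid-August) plus a seasonally
#' damped diel sinusoid (peaking 15:00) plus site-shared hourly AR(1) noise
#' and small sensor-specific white noise. Sensors sit at the four reach
#' boundaries; each reach is labelled by the sensor at its downstream extent.
#' In the post-treatment year the thinned-reach sensor gains a daylight
#' perturbation (a unit plateau over 10:00-20:00 with short shoulders,
#' spanning the hours where the daily maximum occurs) whose amplitude equals
#' the site's realized treatment effect times a seasonal weight, so daily
#' maxima rise by the injected amount in expectation while daily minima
#' (pre-dawn) are untouched; the downstream-reach sensor receives
#' \code{effect_downstream_fraction} of the same perturbation.
#'
#' @param config a [synth_config()].
#' @return list with \code{temps} (hourly logger table as read by
#'   [read_hourly_temps()]) and \code{truth} (injected quantities: nominal
#'   and per-site realized effects by season and reach).
#' @export
synth_temperature <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  hrs <- list(pre = water_year_hours(config$pre_year),
              post = water_year_hours(config$post_year))
  det <- lapply(hrs, synth_deterministic, config = config)
  L <- config$reach_lengths_m
  dist <- c(0, cumsum(unname(L)))                 # four boundary sensors
  sensor_reach <- c("upstream", "upstream", "thinned", "downstream")
  sensor_pos <- c("reach_top", "reach_bottom", "reach_bottom", "reach_bottom")
  site_ids <- sprintf("%s%02d", config$watershed_labels,
                      stats::ave(seq_len(config$n_sites),
                                 config$watershed_labels, FUN = seq_along))
  site_base <- stats::rnorm(config$n_sites, 0, config$site_sd_C)
  site_effect <- stats::rnorm(config$n_sites, config$effect_dmax_C,
                              config$effect_site_sd_C)
  phi <- config$ar1_coef
  innov_sd <- config$noise_sd_C
  blocks <- vector("list", config$n_sites * 2L)
  k <- 0L
  for (s in seq_len(config$n_sites)) {
    for (yr in c("pre", "post")) {
      h <- hrs[[yr]]; d <- det[[yr]]; n <- length(h)
      shared <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                         method = "recursive"))
      eff_amp <- if (yr == "post") site_effect[s] else 0
      mats <- lapply(1:4, function(j) {
        base <- d$annual + d$diel + site_base[s] + 0.05 * (j - 1) + shared +
          stats::rnorm(n, 0, config$sensor_noise_sd_C)
        eff <- switch(j, 0, 0, eff_amp, eff_amp * config$effect_downstream_fraction)
        base + eff * d$effect_shape
      })
      k <- k + 1L
      blocks[[k]] <- list(s = s, n = n, time = as.numeric(h),
                          temp = unlist(mats, use.names = FALSE))
    }
  }
  n_each <- vapply(blocks, `[[`, integer(1), "n")
  s_each <- vapply(blocks, `[[`, integer(1), "s")
  temps <- data.frame(
    watershed = rep(config$watershed_labels[s_each], 4L * n_each),
    site = rep(site_ids[s_each], 4L * n_each),
    reach = unlist(lapply(n_each, function(n) rep(sensor_reach, each = n)),
                   use.names = FALSE),
    position = unlist(lapply(n_each, function(n) rep(sensor_pos, each = n)),
                      use.names = FALSE),
    distance_m = unlist(lapply(n_each, function(n) rep(dist, each = n)),
                        use.names = FALSE),
    timestamp = as.POSIXct(unlist(lapply(blocks, function(b) rep(b$time, 4L)),
                                  use.names = FALSE),
                           origin = "1970-01-01", tz = "UTC"),
    temp_c = unlist(lapply(blocks, `[[`, "temp"), use.names = FALSE)
  )
  if (config$truncate_pre_to_spring_summer) {
    ss <- assign_season(as.Date(temps$timestamp, tz = "UTC"))
    drop <- ss$water_year == config$pre_year &
      ss$season %in% c("Fall", "Winter")
    temps <- temps[!drop, , drop = FALSE]
    rownames(temps) <- NULL
  }
  w <- config$effect_season_weights
  truth <- list(
    config = config,
    site_ids = site_ids,
    site_effect = stats::setNames(site_effect, site_ids),
    effects = data.frame(
      season = rep(season_levels(), 2L),
      reach = rep(c("thinned", "downstream"), each = 4L),
      daily_max_effect_C = c(config$effect_dmax_C * w[season_levels()],
                             config$effect_dmax_C *
                               config$effect_downstream_fraction *
                               w[season_levels()]),
      row.names = NULL
    )
  )
  list(temps = temps, truth = truth)
}

# draw photo fractions around a mean with beta-like bounded noise
rbeta_mean <- function(n, mean_frac, kappa) {
  m <- pmin(pmax(mean_frac, 1e-4), 1 - 1e-4)
  stats::rbeta(n, m * kappa, (1 - m) * kappa)
}

#' Generate shade and light records for a synthetic BACI study
#'
#' Per reach-year, 10-22 hemispherical-photo records with VisSky and GSF drawn
#' around reach means with beta-like bounded noise, and four paired
#' above-/below-canopy pyranometer records (24 hourly values each, a daylight
#' irradiance bell above the canopy). Post-treatment thinned-reach means shift
#' by the configured shade losses and light gain; upstream and downstream
#' reaches keep their pre-treatment canopy.
#'
#' @param config a [synth_config()].
#' @return list with \code{shade} and \code{light} record tables (schemas of
#'   [read_shade_records()] and [read_light_records()]) and \code{truth}
#'   (injected shade/light shifts).
#' @export
synth_shade_light <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  site_ids <- sprintf("%s%02d", config$watershed_labels,
                      stats::ave(seq_len(config$n_sites),
                                 config$watershed_labels, FUN = seq_along))
  reaches <- c("upstream", "thinned", "downstream")
  years <- c(config$pre_year, config$post_year)
  above_bell <- pmax(0, sin(pi * (0:23 - 6) / 14)) * 800  # W/m2, 06:00-20:00
  shade <- list(); light <- list(); k <- 0L
  for (s in seq_len(config$n_sites)) for (r in reaches) for (y in years) {
    thin_post <- r == "thinned" && y == config$post_year
    closure <- config$pre_closure_mean_pct -
      if (thin_post) config$shade_loss_closure_pct else 0
    eshade <- config$pre_effective_shade_pct -
      if (thin_post) config$shade_loss_effective_pct else 0
    trans <- config$pre_transmission_pct +
      if (thin_post) config$light_gain_pct else 0
    n_photo <- sample(10:22, 1L)
    k <- k + 1L
    shade[[k]] <- data.frame(
      site = site_ids[s], reach = r, year = y, photo = seq_len(n_photo),
      vis_sky = rbeta_mean(n_photo, 1 - closure / 100, config$shade_kappa),
      gsf = rbeta_mean(n_photo, 1 - eshade / 100, config$shade_kappa)
    )
    tr <- rbeta_mean(4L, trans / 100, config$shade_kappa * 4)
    light[[k]] <- data.frame(
      site = site_ids[s], reach = r, year = y,
      pyranometer = rep(1:4, each = 24L), hour = rep(0:23, 4L),
      below = rep(tr, each = 24L) * rep(above_bell, 4L),
      above = rep(above_bell, 4L)
    )
  }
  truth <- data.frame(
    metric = c("canopy_closure", "effective_shade", "transmission"),
    thinned_shift_pct = c(-config$shade_loss_closure_pct,
                          -config$shade_loss_effective_pct,
                          config$light_gain_pct)
  )
  list(shade = do.call(rbind, shade), light = do.call(rbind, light),
       truth = truth)
}

#' Generate a complete synthetic BACI study
#'
#' Convenience wrapper producing hourly temperatures, shade and light records,
#' the packaged site covariate table recycled to the configured sites, and the
#' ground-truth object of injected effects.
#'
#' @param config a [synth_config()].
#' @return list with elements \code{temps}, \code{shade}, \code{light},
#'   \code{covariates}, \code{truth}.
#' @export
synth_study <- function(config = synth_config()) {
  tt <- synth_temperature(config)
  sl <- synth_shade_light(config)
  cov <- read_site_covariates()
  cov <- cov[rep_len(seq_len(nrow(cov)), config$n_sites), , drop = FALSE]
  cov$site <- tt$truth$site_ids
  cov$watershed <- config$watershed_labels
  rownames(cov) <- NULL
  truth <- tt$truth
  truth$shade_light <- sl$truth
  list(temps = tt$temps, shade = sl$shade, light = sl$light,
       covariates = cov, truth = truth)
}
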