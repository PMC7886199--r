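# End-to-end analysis: assemble BACI response tables from descriptors, run
# the contrast estimation over responses and seasons (the machine analog of
# the study's response tables), and a one-call driver for a full synthetic
# study.

#' Assemble BACI response data from a descriptor table
#'
#' Extracts one response value per (site, reach, year) for a given descriptor
#' and season, relabelling the two water years as \code{pre}/\code{post}.
#'
#' @param descriptors reach-level descriptor table ([descriptor_table()]).
#' @param response descriptor column name (e.g. \code{"mwmt"}).
#' @param season season name.
#' @param pre_year,post_year water-year labels.
#' @return data frame with columns \code{site}, \code{reach}, \code{year}
#'   (factor pre/post), \code{value}; rows with unavailable values dropped.
#' @export
baci_data <- function(descriptors, response, season, pre_year, post_year) {
  if (!response %in% names(descriptors))
    stop("unknown response descriptor: ", response)
  d <- descriptors[descriptors$season == season &
                     descriptors$water_year %in% c(pre_year, post_year), ,
                   drop = FALSE]
  out <- data.frame(
    site = d$site, reach = as.character(d$reach),
    year = factor(ifelse(d$water_year == pre_year, "pre", "post"),
                  levels = c("pre", "post")),
    value = d[[response]]
  )
  out <- out[is.finite(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BACI contrast table across responses and seasons
#'
#' For every requested response descriptor and season: fits the
#' heteroscedastic BACI mixed model, runs residual diagnostics, and reports
#' the thinned and downstream contrasts with 95 % intervals — Wald by
#' default, switching to the cluster bootstrap when diagnostics reject
#' residual normality (\code{ci = "auto"}). When a season has no
#' pre-treatment data at all (e.g. sensors deployed after the pre-treatment
#' fall), the BACI difference is not estimable and the row instead reports
#' the post-treatment difference between the treated and upstream reach
#' means, flagged \code{type = "post_only"}.
#'
#' @param descriptors reach-level descriptor table.
#' @param responses descriptor columns to analyze (default
#'   [descriptor_names()]).
#' @param seasons seasons to analyze (default all four).
#' @param pre_year,post_year water-year labels.
#' @param ci \code{"auto"} (default), \code{"wald"} or \code{"bootstrap"}.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap.
#' @param level confidence level.
#' @return data frame: one row per (response, season, contrast) with
#'   estimate, lower, upper, method, type, significant.
#' @export
baci_table <- function(descriptors, responses = descriptor_names(),
                       seasons = season_levels(), pre_year, post_year,
                       ci = c("auto", "wald", "bootstrap"), n_boot = 2000L,
                       seed = 1L, level = 0.95) {
  ci <- match.arg(ci)
  rows <- list()
  for (resp in responses) for (ss in seasons) {
    dat <- baci_data(descriptors, resp, ss, pre_year, post_year)
    if (!nrow(dat)) next
    has_pre <- any(dat$year == "pre")
    for (ctr in c("thinned", "downstream")) {
      if (!has_pre) {
        row <- post_only_difference(dat, ctr, level)
      } else if (ci == "bootstrap") {
        row <- baci_bootstrap(dat, ctr, n_boot = n_boot, seed = seed,
                              level = level)
        row$type <- "baci"
      } else {
        fit <- baci_lmm(value ~ reach * year, dat, method = "REML")
        row <- baci_difference(fit, ctr, level = level)
        row$type <- "baci"
        if (ci == "auto") {
          diag <- residual_diagnostics(fit)
          if (isTRUE(diag$recommend_bootstrap)) {
            row <- baci_bootstrap(dat, ctr, n_boot = n_boot, seed = seed,
                                  level = level)
            row$type <- "baci"
          }
        }
      }
      row$response <- resp
      row$season <- ss
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  if (!length(rows)) stop("no response/season combination could be analyzed")
  out <- do.call(rbind, rows)
  out[, c("response", "season", "contrast", "estimate", "lower", "upper",
          "se", "method", "type", "significant")]
}

# post-treatment-only fallback: treated minus upstream reach means across
# sites, t interval
post_only_difference <- function(dat, contrast, level = 0.95) {
  post <- dat[dat$year == "post", , drop = FALSE]
  d <- vapply(split(post, factor(post$site)), function(p) {
    tv <- p$value[p$reach == contrast]
    uv <- p$value[p$reach == "upstream"]
    if (!length(tv) || !length(uv)) return(NA_real_)
    mean(tv) - mean(uv)
  }, numeric(1))
  d <- d[is.finite(d)]
  n <- length(d)
  est <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = max(n - 1L, 1L))
  data.frame(contrast = contrast, estimate = est,
             lower = est - tq * se, upper = est + tq * se, se = se,
             df = n - 1L, method = "wald", type = "post_only",
             significant = (est - tq * se) > 0 | (est + tq * se) < 0)
}

#' Run a complete synthetic BACI study through the pipeline
#'
#' Generates a synthetic study, summarizes shade and light, computes
#' reach- and sensor-level thermal descriptors, estimates BACI contrasts for
#' the requested responses and seasons, builds zero-anchored longitudinal
#' profiles (summer by default), and runs the multivariate regime analysis
#' (NMS + PerMANOVA) per requested season.
#'
#' @param config a [synth_config()].
#' @param responses descriptor columns for the BACI table (default a compact
#'   magnitude set; pass [descriptor_names()] for everything).
#' @param seasons seasons for the BACI table.
#' @param multivariate_seasons seasons for the NMS/PerMANOVA stage (default
#'   \code{"Summer"}); \code{NULL} to skip.
#' @param n_perm PerMANOVA permutations.
#' @param n_boot bootstrap replicates used when diagnostics demand it.
#' @return list with \code{study} (the generated data and truth),
#'   \code{shade_light}, \code{descriptors} (reach level),
#'   \code{sensor_descriptors}, \code{baci}, \code{profiles},
#'   \code{multivariate}.
#' @export
run_baci_study <- function(config = synth_config(),
                           responses = c("avg_daily_max", "mwmt",
                                         "avg_daily_mean", "mwat",
                                         "avg_daily_min"),
                           seasons = season_levels(),
                           multivariate_seasons = "Summer",
                           n_perm = 999L, n_boot = 2000L) {
  study <- synth_study(config)
  temps <- validate_hourly_temps(study$temps)
  sl <- summarize_shade_light(study$shade, study$light)
  desc <- descriptor_table(temps, level = "reach")
  sdesc <- descriptor_table(temps, level = "sensor")
  baci <- baci_table(desc, responses = responses, seasons = seasons,
                     pre_year = config$pre_year,
                     post_year = config$post_year,
                     n_boot = n_boot, seed = config$seed)
  sites <- unique(sdesc$site)
  profiles <- lapply(stats::setNames(sites, sites), function(s)
    longitudinal_profile(sdesc, s, "Summer", config$pre_year,
                         config$post_year, "mwmt"))
  multivariate <- NULL
  if (!is.null(multivariate_seasons)) {
    multivariate <- lapply(stats::setNames(multivariate_seasons,
                                           multivariate_seasons),
                           function(ss) {
      mat <- regime_matrix(desc, season = ss)
      list(matrix = mat,
           nms = regime_nms(mat, seed = config$seed),
           permanova = regime_permanova(mat, n_perm = n_perm,
                                        seed = config$seed))
    })
  }
  list(study = study, shade_light = sl, descriptors = desc,
       sensor_descriptors = sdesc, baci = baci, profiles = profiles,
       multivariate = multivariate)
}
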