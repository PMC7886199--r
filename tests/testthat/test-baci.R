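noiseless_data <- function(cells = c("upstream.pre" = 14, "thinned.pre" = 14,
                                     "downstream.pre" = 14,
                                     "upstream.post" = 15,
                                     "thinned.post" = 17.8,
                                     "downstream.post" = 16.4),
                           site_effects = c(0, 0.5, -0.5, 1)) {
  grid <- expand.grid(site = sprintf("S%d", seq_along(site_effects)),
                      reach = c("upstream", "thinned", "downstream"),
                      year = c("pre", "post"), stringsAsFactors = FALSE)
  grid$value <- cells[paste(grid$reach, grid$year, sep = ".")] +
    site_effects[match(grid$site, unique(grid$site))]
  grid
}

test_that("noiseless additive data recover cell means exactly", {
  dat <- noiseless_data()
  fit <- baci_lmm(value ~ reach * year, dat, method = "ML")
  pred <- predict(fit, expand.grid(reach = c("upstream", "thinned"),
                                   year = c("pre", "post")))
  expect_equal(unname(pred), c(14, 14, 15, 17.8) + mean(c(0, 0.5, -0.5, 1)),
               tolerance = 1e-5)
  expect_true(all(fit$sigma_strata < 1e-4))
})

test_that("the printed double-difference formula gives 2.8 for the toy cells", {
  dat <- noiseless_data()
  fit <- baci_lmm(value ~ reach * year, dat)
  d <- baci_difference(fit, "thinned")
  expect_equal(d$estimate, (17.8 - 14) - (15 - 14), tolerance = 1e-6)
  expect_equal(d$estimate, 2.8, tolerance = 1e-6)
  d2 <- baci_difference(fit, "downstream")
  expect_equal(d2$estimate, (16.4 - 14) - (15 - 14), tolerance = 1e-6)

  # equal cells give exactly zero
  dat0 <- noiseless_data(cells = setNames(
    rep(14, 6), c("upstream.pre", "thinned.pre", "downstream.pre",
                  "upstream.post", "thinned.post", "downstream.post")))
  fit0 <- baci_lmm(value ~ reach * year, dat0)
  expect_equal(baci_difference(fit0, "thinned")$estimate, 0, tolerance = 1e-6)
})

test_that("with equal variances and no site effect the fit matches OLS", {
  set.seed(42)
  dat <- simulate_baci_data(n_sites = 12, cell_means = c("thinned.post" = 1),
                            sd_site = 0, sd_strata = 0.5, seed = 99)
  fit <- baci_lmm(value ~ reach * year, dat, method = "ML",
                  var_strata = "none")
  ols <- lm(value ~ factor(reach, c("upstream", "thinned", "downstream")) *
              factor(year, c("pre", "post")), data = dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("fixed effects and likelihood agree with the nlme cross-check", {
  dat <- simulate_baci_data(n_sites = 10, cell_means = c("thinned.post" = 2),
                            sd_site = 0.5,
                            sd_strata = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                            seed = 3)
  dat$reach <- factor(dat$reach, c("upstream", "thinned", "downstream"))
  dat$year <- factor(dat$year, c("pre", "post"))
  dat$stratum <- interaction(dat$reach, dat$year)
  for (m in c("ML", "REML")) {
    fit <- baci_lmm(value ~ reach * year, dat, method = m)
    ref <- nlme::lme(value ~ reach * year, random = ~ 1 | site,
                     weights = nlme::varIdent(form = ~ 1 | stratum),
                     data = dat, method = m)
    expect_equal(unname(coef(fit)), unname(nlme::fixef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$sigma_site, as.numeric(nlme::VarCorr(ref)[1, 2]),
                 tolerance = 1e-3)
    if (m == "ML")
      expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
})

test_that("variance parameters are recovered in a small simulation", {
  truth_site <- 0.5
  truth_strata <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  est <- replicate(60, NA_real_)
  est_site <- numeric(60)
  est_strata <- matrix(NA_real_, 60, 6)
  for (i in 1:60) {
    dat <- simulate_baci_data(n_sites = 10, sd_site = truth_site,
                              sd_strata = truth_strata, seed = 7000 + i)
    fit <- baci_lmm(value ~ reach * year, dat, method = "REML")
    est_site[i] <- fit$sigma_site
    est_strata[i, ] <- fit$sigma_strata[paste(
      rep(c("upstream", "thinned", "downstream"), 2),
      rep(c("pre", "post"), each = 3), sep = ":")]
  }
  expect_lt(abs(median(est_site) - truth_site) / truth_site, 0.25)
  rel <- abs(apply(est_strata, 2, median) - truth_strata) / truth_strata
  expect_true(all(rel < 0.25))
})

test_that("the Wald estimate equals the plug-in double difference", {
  for (i in 1:10) {
    dat <- simulate_baci_data(n_sites = 8, cell_means = c("thinned.post" = 1.2),
                              sd_site = 0.4,
                              sd_strata = c(0.2, 0.5, 0.3, 0.6, 0.4, 0.7),
                              seed = 300 + i)
    fit <- baci_lmm(value ~ reach * year, dat)
    cm <- tapply(fit$fitted, fit$cell, mean)
    plug <- (cm["thinned:post"] - cm["thinned:pre"]) -
      (cm["upstream:post"] - cm["upstream:pre"])
    expect_equal(baci_difference(fit, "thinned")$estimate, unname(plug),
                 tolerance = 1e-8)
  }
})

test_that("REML optimum beats random perturbations of the variances", {
  dat <- simulate_baci_data(n_sites = 10, sd_site = 0.5,
                            sd_strata = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                            seed = 12)
  fit <- baci_lmm(value ~ reach * year, dat, method = "REML")
  opt <- fit$logLik
  theta_hat <- log(c(fit$sigma_site, fit$sigma_strata))
  set.seed(5)
  for (i in 1:20) {
    theta <- theta_hat + rnorm(length(theta_hat), 0, 0.3)
    refit <- baci_lmm(value ~ reach * year,
                      transform(dat, value = value), method = "REML")
    # evaluate the profiled likelihood at the perturbed variances directly
    pre <- streamtherm:::baci_precompute(
      refit$y, refit$X, as.integer(refit$site), as.integer(refit$stratum))
    val <- -0.5 * streamtherm:::baci_neg2ll(theta, pre, "REML")$neg2ll
    expect_lte(val, opt + 1e-6)
  }
})

test_that("bootstrap intervals are reproducible and degenerate correctly", {
  dat <- simulate_baci_data(n_sites = 10, cell_means = c("thinned.post" = 2),
                            sd_site = 0.5, sd_strata = 0.4, seed = 2)
  b1 <- baci_bootstrap(dat, "thinned", n_boot = 500, seed = 7)
  b2 <- baci_bootstrap(dat, "thinned", n_boot = 500, seed = 7)
  expect_identical(b1, b2)
  b3 <- baci_bootstrap(dat, "thinned", n_boot = 500, seed = 8)
  expect_false(identical(b1$lower, b3$lower))

  # identical sites: zero-width interval at the common double difference
  same <- noiseless_data(site_effects = rep(0, 5))
  bb <- baci_bootstrap(same, "thinned", n_boot = 200, seed = 1)
  expect_equal(bb$lower, bb$upper)
  expect_equal(bb$estimate, 2.8, tolerance = 1e-9)

  one <- same[same$site == "S1", ]
  expect_error(baci_bootstrap(one, "thinned"), "2 distinct sites")
})

test_that("residual diagnostics calibrate and detect heavy tails", {
  gauss_reject <- vapply(1:100, function(i) {
    dat <- simulate_baci_data(n_sites = 10, sd_site = 0.5, sd_strata = 0.5,
                              seed = 800 + i)
    fit <- baci_lmm(value ~ reach * year, dat)
    residual_diagnostics(fit)$normality_rejected
  }, logical(1))
  expect_lte(mean(gauss_reject), 0.10)

  heavy_reject <- vapply(1:100, function(i) {
    set.seed(900 + i)
    dat <- expand.grid(site = sprintf("S%d", 1:10),
                       reach = c("upstream", "thinned", "downstream"),
                       year = c("pre", "post"), stringsAsFactors = FALSE)
    dat$value <- rt(nrow(dat), df = 2) # heavy-tailed
    fit <- baci_lmm(value ~ reach * year, dat)
    residual_diagnostics(fit)$normality_rejected
  }, logical(1))
  expect_gt(mean(heavy_reject), 0.5)

  const <- noiseless_data(site_effects = rep(0, 4))
  fitc <- baci_lmm(value ~ reach * year, const)
  dg <- residual_diagnostics(fitc)
  expect_true(dg$degenerate)
  expect_true(dg$recommend_bootstrap)
})

test_that("model methods behave like a standard fit object", {
  dat <- simulate_baci_data(n_sites = 6, cell_means = c("thinned.post" = 1),
                            sd_site = 0.3, sd_strata = 0.4, seed = 44)
  fit <- baci_lmm(value ~ reach * year, dat)
  expect_length(coef(fit), 6L)
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  expect_equal(length(fitted(fit)), nrow(dat))
  expect_equal(fitted(fit) + residuals(fit), dat$value, tolerance = 1e-9,
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(dat), 3L))
  expect_output(print(fit), "BACI heteroscedastic")
  expect_output(print(summary(fit)), "Coefficient table")
  expect_s3_class(logLik(fit), "logLik")
})

test_that("missing pre-treatment seasons fall back to post-only contrasts", {
  cfg <- small_config(seed = 13, truncate_pre_to_spring_summer = TRUE)
  st <- synth_temperature(cfg)
  desc <- descriptor_table(st$temps, level = "reach",
                           seasons = c("Fall", "Summer"))
  tab <- baci_table(desc, responses = "avg_daily_max",
                    seasons = c("Fall", "Summer"),
                    pre_year = 2016, post_year = 2018,
                    ci = "wald", seed = 1)
  expect_equal(tab$type[tab$season == "Fall"], rep("post_only", 2))
  expect_equal(tab$type[tab$season == "Summer"], rep("baci", 2))
})
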