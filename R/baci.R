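# BACI inference: a Gaussian linear mixed model for the 3x2
# (Reach x Year) design with a random site intercept and stratum-specific
# residual variances, fit by ML or REML with the variance parameters
# profiled against GLS fixed effects and optimized on the log-SD scale.

#' Fit the BACI heteroscedastic linear mixed model
#'
#' Fits \code{value ~ Reach + Year + Reach:Year} with a random intercept per
#' site and residual variances allowed to differ between strata (by default
#' the six Reach-by-Year cells, relaxing constant variance among reaches and
#' years). Reference levels are the upstream reach and the pre-treatment
#' year, so the Reach:Year interaction coefficients are the BACI treatment
#' contrasts. The marginal likelihood is maximized by quasi-Newton descent on
#' log standard deviations, with the fixed effects profiled out by
#' generalized least squares; on apparent non-convergence the optimizer is
#' restarted from perturbed points (3 starts) and the best point is kept with
#' a flag.
#'
#' @param formula model formula, \code{response ~ reach * year} (the design is
#'   fixed; the formula names the response and the two factor columns).
#' @param data data frame with one response value per (site, reach, year) and
#'   a \code{site} column; at least two sites.
#' @param site name of the site (cluster) column, default \code{"site"}.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param var_strata which residual-variance strata to use:
#'   \code{"reach_year"} (default: the six cells), \code{"reach"},
#'   \code{"year"}, or \code{"none"} (homoscedastic).
#' @param reach_levels,year_levels optional explicit factor orderings; by
#'   default the upstream reach and the earliest (or "pre") year are the
#'   reference levels.
#' @return an object of class \code{baci_lmm} with components \code{coef},
#'   \code{vcov}, \code{sigma_site}, \code{sigma_strata}, \code{logLik},
#'   \code{method}, \code{fitted}, \code{residuals}, \code{df_contrast},
#'   \code{converged}, and the model frame.
#' @seealso [baci_difference()], [baci_bootstrap()], [residual_diagnostics()]
#' @export
baci_lmm <- function(formula, data, site = "site",
                     method = c("REML", "ML"),
                     var_strata = c("reach_year", "reach", "year", "none"),
                     reach_levels = NULL, year_levels = NULL) {
  method <- match.arg(method)
  var_strata <- match.arg(var_strata)
  vars <- all.vars(formula)
  if (length(vars) != 3L)
    stop("formula must be of the form response ~ reach * year")
  resp <- vars[1L]; rvar <- vars[2L]; yvar <- vars[3L]
  need <- c(resp, rvar, yvar, site)
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]

  reach <- canonical_factor(data[[rvar]], reach_levels,
                            c("upstream", "thinned", "downstream"))
  year <- canonical_factor(data[[yvar]], year_levels, c("pre", "post"))
  sitef <- factor(data[[site]])
  if (nlevels(sitef) < 2L) stop("need at least 2 sites")
  y <- as.numeric(data[[resp]])

  X <- stats::model.matrix(~ reach * year)
  if (qr(X)$rank < ncol(X)) stop("singular BACI design")
  g <- switch(var_strata,
              reach_year = interaction(reach, year, drop = TRUE, sep = ":"),
              reach = factor(reach), year = factor(year),
              none = factor(rep("all", length(y))))
  gi <- as.integer(g); G <- nlevels(g)
  si <- as.integer(sitef)

  # -2 log likelihood profiled over beta; theta = log SDs (site, strata)
  pre <- baci_precompute(y, X, si, gi)
  obj <- function(theta)
    tryCatch(baci_neg2ll(theta, pre, method)$neg2ll,
             error = function(e) 1e10)
  s0 <- stats::sd(stats::resid(stats::lm.fit(X, y)))
  if (!is.finite(s0) || s0 <= 0) s0 <- 1e-3
  start <- rep(log(s0), G + 1L)
  lower <- rep(log(1e-6), G + 1L)
  upper <- rep(log(1e3), G + 1L)
  fit0 <- stats::nlminb(start, obj, lower = lower, upper = upper,
                        control = list(rel.tol = 1e-8, iter.max = 500))
  best <- fit0; converged <- fit0$convergence == 0
  if (!converged) {
    set.seed(17L) # deterministic restarts
    for (i in 1:3) {
      f <- stats::nlminb(start + stats::rnorm(G + 1L, 0, 0.5), obj,
                         lower = lower, upper = upper,
                         control = list(rel.tol = 1e-8, iter.max = 500))
      if (f$objective < best$objective) best <- f
      if (f$convergence == 0) { converged <- TRUE; break }
    }
  }
  theta <- best$par
  ll <- baci_neg2ll(theta, pre, method)

  cellkey <- interaction(reach, year, sep = ":")
  fitted <- drop(X %*% ll$beta)
  # BLUPs of the site intercepts and conditional residuals
  rmarg <- y - fitted
  s2site <- exp(2 * theta[1L]); s2g <- exp(2 * theta[-1L])
  blup <- vapply(split(seq_along(y), si), function(i) {
    Vs <- diag(s2g[gi[i]] + 1e-10 * (s2site + max(s2g)), length(i)) + s2site
    s2site * sum(solve(Vs, rmarg[i]))
  }, numeric(1))
  out <- list(
    call = match.call(), formula = formula, method = method,
    var_strata = var_strata,
    coef = stats::setNames(drop(ll$beta), colnames(X)),
    vcov = structure(ll$vcov_beta,
                     dimnames = list(colnames(X), colnames(X))),
    sigma_site = exp(theta[1L]),
    sigma_strata = stats::setNames(exp(theta[-1L]), levels(g)),
    logLik = -0.5 * best$objective,
    n = length(y), p = ncol(X), n_sites = nlevels(sitef),
    df_contrast = length(y) - ncol(X) - nlevels(sitef) + 1L,
    fitted = fitted, residuals = rmarg,
    ranef = stats::setNames(blup, levels(sitef)),
    residuals_cond = rmarg - blup[si],
    stratum = g, site = sitef, reach = reach, year = year, y = y, X = X,
    cell = cellkey, converged = converged,
    convergence_message = best$message
  )
  class(out) <- "baci_lmm"
  out
}

# Pre-compute the theta-independent cross-products of the block-wise marginal
# likelihood. Sites are grouped by their stratum pattern (identical for all
# sites in a balanced 3x2 design): within a group every site shares the same
# block covariance V_b = diag(sigma_g^2) + sigma_site^2 J, so each likelihood
# evaluation only needs one small chol per group plus weighted sums of the
# pre-computed products X_a' X_b, X_a' y_b, y_a' y_b over within-block row
# positions a, b.
baci_precompute <- function(y, X, si, gi) {
  p <- ncol(X)
  groups <- list()
  for (s in unique(si)) {
    i <- which(si == s)
    i <- i[order(gi[i])]
    key <- paste(gi[i], collapse = ",")
    groups[[key]] <- c(groups[[key]], list(i))
  }
  pats <- lapply(names(groups), function(key) {
    idx <- groups[[key]]
    q <- length(idx[[1L]])
    m <- length(idx)
    gpat <- gi[idx[[1L]]]
    # rows at within-block position a across the group's sites: m x p / m x 1
    Xa <- lapply(seq_len(q), function(a)
      X[vapply(idx, `[`, integer(1), a), , drop = FALSE])
    ya <- lapply(seq_len(q), function(a) y[vapply(idx, `[`, integer(1), a)])
    PP <- Py <- vector("list", q * q)
    yy <- matrix(0, q, q)
    for (a in seq_len(q)) for (b in seq_len(q)) {
      PP[[(a - 1L) * q + b]] <- crossprod(Xa[[a]], Xa[[b]])
      Py[[(a - 1L) * q + b]] <- drop(crossprod(Xa[[a]], ya[[b]]))
      yy[a, b] <- sum(ya[[a]] * ya[[b]])
    }
    list(q = q, m = m, gpat = gpat, PP = PP, Py = Py, yy = yy)
  })
  list(pats = pats, p = p, n = length(y))
}

baci_neg2ll <- function(theta, pre, method) {
  s2site <- exp(2 * theta[1L])
  s2g <- exp(2 * theta[-1L])
  p <- pre$p; n <- pre$n
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); yVy <- 0; logdet <- 0
  for (pat in pre$pats) {
    q <- pat$q
    # tiny relative ridge keeps the block Cholesky stable when stratum
    # variances collapse to the boundary while the site variance stays large
    ridge <- 1e-10 * (s2site + max(s2g))
    Vb <- diag(s2g[pat$gpat] + ridge, q) + s2site
    R <- chol(Vb)
    logdet <- logdet + pat$m * 2 * sum(log(diag(R)))
    W <- chol2inv(R)
    for (a in seq_len(q)) for (b in seq_len(q)) {
      w <- W[a, b]
      if (w == 0) next
      k <- (a - 1L) * q + b
      XtVX <- XtVX + w * pat$PP[[k]]
      XtVy <- XtVy + w * pat$Py[[k]]
      yVy <- yVy + w * pat$yy[a, b]
    }
  }
  cR <- chol(XtVX)
  beta <- backsolve(cR, backsolve(cR, XtVy, transpose = TRUE))
  quad <- yVy - sum(beta * XtVy)
  neg2ll <- if (method == "ML")
    logdet + quad + n * log(2 * pi)
  else
    logdet + 2 * sum(log(diag(cR))) + quad + (n - p) * log(2 * pi)
  list(neg2ll = neg2ll, beta = beta, vcov_beta = chol2inv(cR))
}

canonical_factor <- function(x, levels_arg, preferred) {
  if (!is.null(levels_arg)) return(factor(x, levels = levels_arg))
  u <- unique(as.character(x))
  if (all(u %in% preferred))
    factor(as.character(x), levels = intersect(preferred, u))
  else
    factor(x, levels = sort(u)) # e.g. calendar years: earliest = reference
}

#' BACI difference (treatment contrast) with confidence interval
#'
#' The BACI difference for a treated reach is the double difference
#' \code{(TreatedPost - TreatedPre) - (UpstreamPost - UpstreamPre)}, which
#' under reference coding equals the Reach:Year interaction coefficient for
#' that reach. The Wald interval uses the contrast's model standard error on
#' a t reference with \code{n - p - n_sites + 1} degrees of freedom (a
#' small-sample-conservative choice for ten-site designs). The effect is
#' declared significant when the interval excludes zero.
#'
#' @param fit a [baci_lmm()] fit.
#' @param contrast \code{"thinned"} or \code{"downstream"}.
#' @param level confidence level (default 0.95).
#' @return a one-row data frame of class \code{baci_difference}: contrast,
#'   estimate, lower, upper, se, df, method ("wald"), significant.
#' @export
baci_difference <- function(fit, contrast = c("thinned", "downstream"),
                            level = 0.95) {
  stopifnot(inherits(fit, "baci_lmm"))
  contrast <- match.arg(contrast)
  post <- levels(fit$year)[2L]
  nm <- paste0("reach", contrast, ":year", post)
  if (!nm %in% names(fit$coef))
    stop("unknown contrast term: ", nm)
  est <- unname(fit$coef[nm])
  se <- sqrt(fit$vcov[nm, nm])
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df_contrast)
  out <- data.frame(contrast = contrast, estimate = est,
                    lower = est - tq * se, upper = est + tq * se,
                    se = se, df = fit$df_contrast, method = "wald",
                    significant = (est - tq * se) > 0 | (est + tq * se) < 0)
  class(out) <- c("baci_difference", "data.frame")
  out
}

#' Cluster-bootstrap confidence interval for a BACI difference
#'
#' Resamples whole sites with replacement (the site is the independent
#' replicate) and recomputes the plug-in double difference of resampled cell
#' means per replicate; the interval is the percentile interval of the
#' bootstrap distribution. Used when residual diagnostics reject normality.
#'
#' @param data BACI data frame with columns \code{site}, \code{reach},
#'   \code{year}, and the response named by \code{response}.
#' @param contrast \code{"thinned"} or \code{"downstream"}.
#' @param response name of the response column (default \code{"value"}).
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed; the interval is seed-reproducible.
#' @param level confidence level (default 0.95).
#' @return a one-row \code{baci_difference} data frame (method
#'   \code{"bootstrap"}).
#' @export
baci_bootstrap <- function(data, contrast = c("thinned", "downstream"),
                           response = "value", n_boot = 2000L, seed = 1L,
                           level = 0.95) {
  contrast <- match.arg(contrast)
  contrib <- site_double_diffs(data, contrast, response)
  ns <- length(contrib)
  if (ns < 2L) stop("cluster bootstrap needs at least 2 distinct sites")
  set.seed(seed)
  idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), nrow = ns)
  stat <- colMeans(matrix(contrib[idx], nrow = ns))
  est <- mean(contrib)
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  out <- data.frame(contrast = contrast, estimate = est,
                    lower = qs[1L], upper = qs[2L],
                    se = stats::sd(stat), df = NA_real_,
                    method = "bootstrap",
                    significant = qs[1L] > 0 | qs[2L] < 0)
  class(out) <- c("baci_difference", "data.frame")
  out
}

# per-site plug-in double differences (Treated post-pre minus Upstream
# post-pre); sites missing any of the four cells are dropped
site_double_diffs <- function(data, contrast, response = "value") {
  reach <- canonical_factor(data$reach, NULL,
                            c("upstream", "thinned", "downstream"))
  year <- canonical_factor(data$year, NULL, c("pre", "post"))
  pre <- levels(year)[1L]; post <- levels(year)[2L]
  v <- as.numeric(data[[response]])
  out <- vapply(split(seq_len(nrow(data)), factor(data$site)), function(i) {
    cell <- function(r, yy) {
      j <- i[reach[i] == r & year[i] == yy]
      if (!length(j)) return(NA_real_)
      mean(v[j])
    }
    (cell(contrast, post) - cell(contrast, pre)) -
      (cell("upstream", post) - cell("upstream", pre))
  }, numeric(1))
  out[is.finite(out)]
}

#' Residual diagnostics for a BACI fit
#'
#' Normality check on the conditional residuals (marginal residuals minus
#' the site-intercept BLUPs). Within each residual-variance stratum the
#' residuals are externally studentized (each scaled by the leave-one-out
#' SD of its stratum, so an outlier cannot mask itself by inflating its own
#' scale estimate) and mapped through the t CDF to normal quantiles; the
#' Shapiro-Wilk test is applied to the pooled standardized values. The
#' stratum-SD ratio summarizes the fitted heteroscedasticity. When
#' normality is rejected at \code{alpha} (or the residuals are degenerate),
#' the cluster-bootstrap interval is recommended over the Wald interval,
#' mirroring the practice of falling back to a bootstrapping protocol for
#' non-normal responses.
#'
#' @param fit a [baci_lmm()] fit.
#' @param alpha rejection level for the normality test (default 0.05).
#' @return list with \code{shapiro_w}, \code{shapiro_p},
#'   \code{normality_rejected}, \code{variance_ratio}, \code{degenerate},
#'   \code{recommend_bootstrap}.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "baci_lmm"))
  r <- fit$residuals_cond
  degenerate <- stats::sd(r) < 1e-10
  if (degenerate) {
    return(list(shapiro_w = NA_real_, shapiro_p = NA_real_,
                normality_rejected = NA, variance_ratio = NA_real_,
                degenerate = TRUE, recommend_bootstrap = TRUE))
  }
  g <- as.integer(fit$stratum)
  z <- numeric(length(r))
  for (k in unique(g)) {
    i <- which(g == k)
    n <- length(i)
    if (n < 3L) { # too few points to studentize: model-SD scaling
      z[i] <- r[i] / pmax(fit$sigma_strata[k], 1e-12)
      next
    }
    for (j in seq_along(i)) {
      s <- stats::sd(r[i][-j])
      tval <- r[i[j]] / max(s * sqrt(1 + 1 / (n - 1)), 1e-12)
      z[i[j]] <- stats::qnorm(pmin(pmax(stats::pt(tval, df = n - 2L),
                                        1e-12), 1 - 1e-12))
    }
  }
  sw <- stats::shapiro.test(z)
  vr <- max(fit$sigma_strata) / max(min(fit$sigma_strata), 1e-12)
  rejected <- sw$p.value < alpha
  list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       normality_rejected = rejected, variance_ratio = vr,
       degenerate = FALSE, recommend_bootstrap = rejected)
}

#' Simulate BACI response data with known cell means
#'
#' Draws one response per (site, reach, year): cell mean + a site random
#' intercept + stratum-specific Gaussian noise. Useful for calibration and
#' parameter-recovery studies of the BACI estimators at the response level.
#'
#' @param n_sites number of sites.
#' @param cell_means named numeric vector of the six cell means with names
#'   \code{"upstream.pre"}, \code{"thinned.pre"}, \code{"downstream.pre"},
#'   \code{"upstream.post"}, \code{"thinned.post"}, \code{"downstream.post"}
#'   (missing cells default to 0).
#' @param sd_site SD of the site random intercept.
#' @param sd_strata residual SD per cell, recycled to six values (ordered as
#'   \code{cell_means} above).
#' @param seed integer seed.
#' @return data frame with columns \code{site}, \code{reach}, \code{year},
#'   \code{value}.
#' @export
simulate_baci_data <- function(n_sites = 10L, cell_means = c(),
                               sd_site = 0.5, sd_strata = 0.4, seed = 1L) {
  cells <- as.vector(outer(c("upstream", "thinned", "downstream"),
                           c("pre", "post"), paste, sep = "."))
  mu <- stats::setNames(rep(0, 6L), cells)
  if (length(cell_means)) {
    bad <- setdiff(names(cell_means), cells)
    if (length(bad)) stop("unknown cell name(s): ", paste(bad, collapse = ", "))
    mu[names(cell_means)] <- cell_means
  }
  sdg <- stats::setNames(rep_len(sd_strata, 6L), cells)
  set.seed(seed)
  b <- stats::rnorm(n_sites, 0, sd_site)
  grid <- expand.grid(site = sprintf("S%02d", seq_len(n_sites)),
                      reach = c("upstream", "thinned", "downstream"),
                      year = c("pre", "post"), stringsAsFactors = FALSE)
  cell <- paste(grid$reach, grid$year, sep = ".")
  grid$value <- mu[cell] + b[match(grid$site, unique(grid$site))] +
    stats::rnorm(nrow(grid), 0, sdg[cell])
  rownames(grid) <- NULL
  grid
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.baci_lmm <- function(x, ...) {
  cat("BACI heteroscedastic linear mixed model (", x$method, ")\n", sep = "")
  cat("  sites:", x$n_sites, " observations:", x$n, "\n")
  cat("  random site intercept SD:", format(x$sigma_site, digits = 4), "\n")
  cat("  residual SD by stratum:\n")
  print(round(x$sigma_strata, 4))
  cat("  fixed effects:\n")
  print(round(x$coef, 4))
  if (!x$converged)
    cat("  WARNING: optimizer did not report convergence (best point kept)\n")
  invisible(x)
}

#' @export
summary.baci_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coef, `Std.Error` = se,
               `t value` = object$coef / se)
  structure(list(fit = object, coefficients = tab,
                 logLik = object$logLik, method = object$method),
            class = "summary.baci_lmm")
}

#' @export
print.summary.baci_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coefficients)
  cat("\nlogLik (", x$method, "): ", format(x$logLik, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.baci_lmm <- function(object, ...) object$coef

#' @export
vcov.baci_lmm <- function(object, ...) object$vcov

#' @export
logLik.baci_lmm <- function(object, ...) {
  structure(object$logLik,
            df = object$p + length(object$sigma_strata) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.baci_lmm <- function(object, ...) object$fitted

#' @export
residuals.baci_lmm <- function(object,
                               type = c("response", "pearson",
                                        "conditional", "normalized"), ...) {
  type <- match.arg(type)
  sg <- object$sigma_strata[as.integer(object$stratum)]
  r <- switch(type,
              response = object$residuals,
              pearson = object$residuals / sg,
              conditional = object$residuals_cond,
              normalized = object$residuals_cond / sg)
  unname(r)
}

#' Population-level predictions from a BACI fit
#'
#' @param object a [baci_lmm()] fit.
#' @param newdata optional data frame with \code{reach} and \code{year}
#'   columns; defaults to the model frame.
#' @param ... unused.
#' @return numeric vector of predicted cell means (random effects set to 0).
#' @export
predict.baci_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  reach <- factor(newdata$reach, levels = levels(object$reach))
  year <- factor(newdata$year, levels = levels(object$year))
  X <- stats::model.matrix(~ reach * year)
  drop(X %*% object$coef)
}

#' Parametric simulation from a fitted BACI model
#'
#' @param object a [baci_lmm()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with \code{nsim} columns of simulated responses, rows
#'   aligned with the model frame.
#' @export
simulate.baci_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  si <- as.integer(object$site)
  sg <- object$sigma_strata[as.integer(object$stratum)]
  out <- as.data.frame(replicate(nsim, {
    b <- stats::rnorm(object$n_sites, 0, object$sigma_site)
    object$fitted + b[si] + stats::rnorm(object$n, 0, sg)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.baci_difference <- function(x, ...) {
  cat(sprintf("BACI difference (%s, %s): %.3f [%.3f, %.3f]%s\n",
              x$contrast, x$method, x$estimate, x$lower, x$upper,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
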