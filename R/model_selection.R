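# Environmental-covariate analysis: Pearson correlation screening,
# collinearity pruning (|r| > 0.6) and VIF checks, then AICc ranking of a
# priori candidate fixed-effect models (random site intercept), ML for
# ranking and an REML refit of the best model for reported coefficients.

#' Pearson correlation matrix of covariates and responses
#'
#' @param data data frame; non-numeric columns are dropped.
#' @return symmetric correlation matrix (diagonal 1). Zero-variance
#'   variables get \code{NA} rows/columns and are listed in the
#'   \code{"flagged"} attribute.
#' @export
correlation_matrix <- function(data) {
  num <- data[, vapply(data, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 2L) stop("need at least two numeric variables")
  if (nrow(num) < 3L) stop("need at least 3 complete rows")
  sds <- vapply(num, stats::sd, numeric(1), na.rm = TRUE)
  flagged <- names(num)[!is.finite(sds) | sds < 1e-12]
  r <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
  if (length(flagged)) {
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
    diag(r) <- 1
  }
  attr(r, "flagged") <- flagged
  r
}

#' Prune candidate covariate sets containing highly correlated pairs
#'
#' Any candidate set containing a pair of covariates with \code{|r|} above
#' the threshold is rejected, and the offending pair is named. Singleton
#' sets are always retained.
#'
#' @param sets named list of character vectors (covariate sets).
#' @param cormat correlation matrix covering all covariates used.
#' @param r_threshold rejection threshold on \code{|r|} (default 0.6).
#' @return list with \code{retained} (subset of \code{sets}) and
#'   \code{rejected} (data frame naming each rejected set and its worst
#'   offending pair).
#' @export
prune_correlated <- function(sets, cormat, r_threshold = 0.6) {
  if (is.null(names(sets))) names(sets) <- vapply(sets, paste, "", collapse = "+")
  rej <- list()
  keep <- logical(length(sets))
  for (i in seq_along(sets)) {
    v <- sets[[i]]
    keep[i] <- TRUE
    if (length(v) < 2L) next
    pairs <- utils::combn(v, 2L)
    rr <- abs(cormat[cbind(pairs[1L, ], pairs[2L, ])])
    bad <- which(is.finite(rr) & rr > r_threshold)
    if (length(bad)) {
      keep[i] <- FALSE
      w <- bad[which.max(rr[bad])]
      rej[[length(rej) + 1L]] <- data.frame(
        set = names(sets)[i], var1 = pairs[1L, w], var2 = pairs[2L, w],
        r = cormat[pairs[1L, w], pairs[2L, w]])
    }
  }
  list(retained = sets[keep],
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(set = character(), var1 = character(),
                                  var2 = character(), r = numeric()))
}

#' Variance inflation factors
#'
#' \code{VIF_j = 1 / (1 - R2_j)} from regressing covariate j on the other
#' covariates. Perfect collinearity yields an infinite VIF, reported with a
#' warning.
#'
#' @param data data frame or matrix of covariate columns (>= 2).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(data) {
  X <- as.matrix(data)
  p <- ncol(X)
  if (p < 2L) stop("VIF needs at least two covariates")
  if (nrow(X) < p + 2L) stop("need at least p + 2 rows for p covariates")
  out <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out)))
    warning("perfect collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Small-sample-corrected Akaike information criterion
#'
#' \code{AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)}.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects + variance
#'   components).
#' @param n sample size.
#' @return AICc value; \code{NA} with a warning when \code{n - k - 1 <= 0}.
#' @export
#' @examples
#' aicc(-10, 3, 20) # 27.5
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined: n - k - 1 <= 0")
    return(NA_real_)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate mixed models by AICc
#'
#' Fits each a priori candidate fixed-effect structure as a linear mixed
#' model with a random site intercept, by Maximum Likelihood (the
#' likelihoods are then comparable across fixed effects), ranks by AICc, and
#' refits the best-supported model with REML for reported coefficients. The
#' parameter count k is the number of fixed-effect coefficients plus two
#' variance components (site intercept, residual); n is the number of
#' response rows. Ties (delta AICc < 1e-6) are broken by smaller k.
#'
#' @param candidates named list of right-hand sides: character vectors of
#'   covariate names (use \code{character(0)} or \code{"1"} for the null
#'   intercept-only model, or a one-sided formula such as
#'   \code{~ reach * year} for the BACI model).
#' @param data data frame containing the response, covariates and a site
#'   column.
#' @param response name of the response column.
#' @param site name of the site (random intercept) column, default "site".
#' @return object of class \code{aicc_ranking}: \code{table} (model, k,
#'   logLik, AICc, delta, weight, sorted ascending), \code{fits} (ML fits),
#'   \code{best} (model name) and \code{best_reml} (REML refit).
#' @export
rank_models <- function(candidates, data, response, site = "site") {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a fully named list")
  n <- nrow(data)
  rows <- list(); fits <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    fixed <- if (inherits(cand, "formula"))
      stats::as.formula(paste(response, "~",
                              paste(deparse(cand[[2L]]), collapse = " ")))
    else if (!length(cand) || identical(cand, "1"))
      stats::reformulate("1", response = response)
    else stats::reformulate(cand, response = response)
    random <- stats::as.formula(paste0("~ 1 | ", site))
    fit <- nlme::lme(fixed = fixed, random = random, data = data,
                     method = "ML")
    fit$streamtherm_fixed <- fixed
    kf <- length(nlme::fixef(fit))
    k <- kf + 2L # + site-intercept variance + residual variance
    a <- aicc(as.numeric(stats::logLik(fit)), k, n)
    if (is.na(a)) {
      warning("candidate '", nm, "' excluded: AICc undefined at n = ", n)
      next
    }
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, k = k,
                             logLik = as.numeric(stats::logLik(fit)),
                             AICc = a)
  }
  if (!length(rows)) stop("no candidate could be fit")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc, tab$k), , drop = FALSE]
  tab$delta <- tab$AICc - tab$AICc[1L]
  w <- exp(-0.5 * tab$delta)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  best <- tab$model[1L]
  best_reml <- nlme::lme(fixed = fits[[best]]$streamtherm_fixed,
                         random = stats::as.formula(paste0("~ 1 | ", site)),
                         data = data, method = "REML")
  out <- list(table = tab, fits = fits, best = best, best_reml = best_reml,
              n = n)
  class(out) <- "aicc_ranking"
  out
}

#' @export
print.aicc_ranking <- function(x, ...) {
  cat("AICc model ranking (n =", x$n, "):\n")
  tab <- x$table
  tab$logLik <- round(tab$logLik, 3)
  tab$AICc <- round(tab$AICc, 3)
  tab$delta <- round(tab$delta, 3)
  tab$weight <- round(tab$weight, 4)
  print(tab)
  cat("Best-supported model:", x$best, "(coefficients from REML refit)\n")
  invisible(x)
}
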