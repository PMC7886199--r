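# Thermal-regime structure: descriptor matrix assembly, non-metric
# multidimensional scaling (NMS) in two dimensions on Euclidean distances,
# reach-level confidence ellipses, and a PerMANOVA test of the Reach x Year
# (BACI) effect.

#' Assemble the standardized thermal-regime descriptor matrix
#'
#' One row per retained (site, reach, water year, season) combination,
#' columns the selected descriptors. Because the descriptors mix units
#' (deg C, deg C squared, day counts), columns are z-standardized by default
#' before Euclidean distances are computed; the means and SDs are stored.
#' Rows with any unavailable descriptor are dropped (count reported via
#' message); constant columns cannot be standardized and are dropped with a
#' warning.
#'
#' @param descriptors reach-level descriptor table from [descriptor_table()].
#' @param descriptor_list descriptor columns to use (default the standard 14
#'   of [descriptor_names()]).
#' @param season optional season filter (e.g. \code{"Summer"}); default all.
#' @param standardize z-score the columns (default TRUE).
#' @return object of class \code{regime_matrix}: list with \code{x} (numeric
#'   matrix), \code{labels} (site/reach/year/season per row), \code{center},
#'   \code{scale}, \code{dropped_rows}, \code{dropped_cols}.
#' @export
regime_matrix <- function(descriptors, descriptor_list = descriptor_names(),
                          season = NULL, standardize = TRUE) {
  absent <- setdiff(descriptor_list, names(descriptors))
  if (length(absent))
    stop("descriptor(s) absent from table: ", paste(absent, collapse = ", "))
  d <- descriptors
  if (!is.null(season)) d <- d[d$season %in% season, , drop = FALSE]
  if (!nrow(d)) stop("no rows after season filter")
  x <- as.matrix(d[, descriptor_list, drop = FALSE])
  keep <- stats::complete.cases(x)
  dropped_rows <- sum(!keep)
  if (dropped_rows)
    message(dropped_rows, " row(s) dropped for unavailable descriptors")
  x <- x[keep, , drop = FALSE]
  d <- d[keep, , drop = FALSE]
  if (!nrow(x)) stop("no complete rows for the requested descriptors")
  dropped_cols <- character()
  center <- scale_ <- NULL
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    const <- sds < 1e-12 | !is.finite(sds)
    if (any(const)) {
      dropped_cols <- colnames(x)[const]
      warning("constant column(s) dropped: ",
              paste(dropped_cols, collapse = ", "))
      x <- x[, !const, drop = FALSE]
    }
    xs <- scale(x)
    center <- attr(xs, "scaled:center")
    scale_ <- attr(xs, "scaled:scale")
    x <- xs[, , drop = FALSE]
    attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  }
  out <- list(x = x,
              labels = data.frame(site = d$site, reach = d$reach,
                                  water_year = d$water_year,
                                  season = as.character(d$season)),
              center = center, scale = scale_,
              dropped_rows = dropped_rows, dropped_cols = dropped_cols,
              standardized = standardize)
  class(out) <- "regime_matrix"
  out
}

#' @export
print.regime_matrix <- function(x, ...) {
  cat("Thermal-regime matrix:", nrow(x$x), "rows x", ncol(x$x),
      "descriptors", if (x$standardized) "(z-standardized)" else "(raw)", "\n")
  invisible(x)
}

#' Non-metric multidimensional scaling of a regime matrix
#'
#' Two-dimensional NMS on Euclidean distances, minimizing Kruskal stress-1
#' between the input distances and monotone-regressed configuration
#' distances. The first start is the metric (principal-coordinates)
#' configuration, followed by random restarts (up to \code{max_restarts},
#' the iterative optimization budget); the search stops early once two
#' solutions agree within \code{stress_tol} stress. Coordinates are centered
#' at the origin.
#'
#' @param mat a [regime_matrix()] or a plain numeric matrix.
#' @param k number of dimensions (default 2).
#' @param max_restarts restart budget (default 999).
#' @param seed integer seed; results are seed-reproducible.
#' @param stress_tol early-stopping tolerance on stress (default 1e-4).
#' @return object of class \code{regime_nms}: \code{points} (centered
#'   coordinates), \code{stress} (Kruskal stress-1), \code{n_starts},
#'   \code{converged}, \code{seed}, \code{labels} (if available).
#' @export
regime_nms <- function(mat, k = 2L, max_restarts = 999L, seed = 42L,
                       stress_tol = 1e-4) {
  x <- if (inherits(mat, "regime_matrix")) mat$x else as.matrix(mat)
  labels <- if (inherits(mat, "regime_matrix")) mat$labels else NULL
  if (nrow(x) < k + 1L) stop("need at least k + 1 rows")
  d <- stats::dist(x)
  if (max(d) < 1e-12) stop("degenerate input: all rows identical")
  set.seed(seed)
  n <- nrow(x)
  start <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
  if (is.null(start) || ncol(start) < k)
    start <- matrix(stats::rnorm(n * k), n, k)
  best <- vegan::monoMDS(d, y = start, k = k, model = "global",
                         maxit = 500, smin = 1e-5, sratmax = 1 - 1e-6)
  n_starts <- 1L; converged <- FALSE
  for (i in seq_len(max_restarts - 1L)) {
    y0 <- matrix(stats::rnorm(n * k), n, k)
    cand <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                           maxit = 500, smin = 1e-5, sratmax = 1 - 1e-6)
    n_starts <- n_starts + 1L
    if (abs(cand$stress - best$stress) < stress_tol ||
        (cand$stress < best$stress + stress_tol && best$stress < stress_tol)) {
      if (cand$stress < best$stress) best <- cand
      converged <- TRUE
      break
    }
    if (cand$stress < best$stress) best <- cand
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("NMS", seq_len(k))
  out <- list(points = pts, stress = best$stress, n_starts = n_starts,
              converged = converged, seed = seed, labels = labels)
  class(out) <- "regime_nms"
  out
}

#' @export
print.regime_nms <- function(x, ...) {
  cat(sprintf("NMS ordination: %d points, %d dims, stress-1 = %.4f (%d starts%s)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Normal-theory confidence ellipses per group
#'
#' For each group with at least three points, the 95 % (by default)
#' normal-theory ellipse: group mean, covariance, and chi-square radius
#' \code{sqrt(qchisq(level, 2))}. Groups with fewer than three points are
#' skipped with a warning; singular covariances (collinear points) are
#' flagged degenerate.
#'
#' @param ordination a [regime_nms()] result or a 2-column coordinate matrix.
#' @param groups grouping labels, one per row (e.g. reach).
#' @param level confidence level (default 0.95).
#' @return named list of ellipses: \code{center}, \code{cov}, \code{radius},
#'   \code{n}, \code{degenerate}.
#' @export
group_ellipses <- function(ordination, groups, level = 0.95) {
  pts <- if (inherits(ordination, "regime_nms")) ordination$points
         else as.matrix(ordination)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(pts))
  out <- list()
  for (gname in unique(groups)) {
    p <- pts[groups == gname, , drop = FALSE]
    if (nrow(p) < 3L) {
      warning("group '", gname, "' has fewer than 3 points; skipped")
      next
    }
    S <- stats::cov(p)
    out[[gname]] <- list(center = colMeans(p), cov = S,
                         radius = sqrt(stats::qchisq(level, df = ncol(p))),
                         n = nrow(p),
                         degenerate = det(S) < 1e-12)
  }
  out
}

#' Does an ellipse contain given points?
#'
#' @param ellipse one element of [group_ellipses()].
#' @param points matrix of points (columns matching the ordination axes).
#' @return logical vector: Mahalanobis distance within the ellipse radius.
#' @export
ellipse_contains <- function(ellipse, points) {
  if (ellipse$degenerate) stop("degenerate ellipse")
  md2 <- stats::mahalanobis(as.matrix(points), ellipse$center, ellipse$cov)
  md2 <= ellipse$radius^2
}

#' PerMANOVA test of the Reach x Year (BACI) structure effect
#'
#' Partitions squared Euclidean distances among rows of the regime matrix by
#' the Reach + Year + Reach:Year design and tests each term by permutation:
#' \code{p = (count of permuted pseudo-F >= observed + 1) / (n_perm + 1)}.
#' By default rows are permuted freely (the convention of common PerMANOVA
#' implementations, and the test used for the interaction); a more
#' conservative scheme restricting permutations within sites is available.
#'
#' @param mat a [regime_matrix()] (its labels supply Reach/Year/site) or a
#'   plain matrix with \code{labels} supplied.
#' @param labels optional data frame with \code{reach}, \code{water_year} and
#'   \code{site} columns (required when \code{mat} is a plain matrix).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param within_site restrict permutations to within-site exchanges
#'   (default FALSE, free permutation).
#' @return object of class \code{regime_permanova}: \code{table} (term, df,
#'   SS, R2, pseudo-F, p), \code{n_perm}, \code{seed}.
#' @export
regime_permanova <- function(mat, labels = NULL, n_perm = 999L, seed = 42L,
                             within_site = FALSE) {
  x <- if (inherits(mat, "regime_matrix")) mat$x else as.matrix(mat)
  if (is.null(labels) && inherits(mat, "regime_matrix")) labels <- mat$labels
  if (is.null(labels)) stop("labels required")
  df <- data.frame(reach = factor(labels$reach),
                   year = factor(labels$water_year))
  set.seed(seed)
  perm <- if (within_site)
    permute::how(blocks = factor(labels$site), nperm = n_perm)
  else n_perm
  res <- vegan::adonis2(x ~ reach + year + reach:year, data = df,
                        permutations = perm, method = "euclidean",
                        by = "terms")
  tab <- data.frame(term = rownames(res), df = res$Df, ss = res$SumOfSqs,
                    r2 = res$R2, pseudo_f = res$F, p = res$`Pr(>F)`,
                    row.names = NULL)
  out <- list(table = tab, n_perm = n_perm, seed = seed,
              within_site = within_site)
  class(out) <- "regime_permanova"
  out
}

#' @export
print.regime_permanova <- function(x, ...) {
  cat("PerMANOVA (Euclidean,", x$n_perm, "permutations",
      if (x$within_site) ", within-site" else "", ")\n", sep = "")
  print(transform(x$table, ss = round(ss, 4), r2 = round(r2, 4),
                  pseudo_f = round(pseudo_f, 3)))
  invisible(x)
}
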