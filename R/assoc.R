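#' Partial Pearson correlation controlling for covariates
#'
#' Residualises x and y on an intercept plus the covariate columns by least
#' squares, correlates the residuals, and tests with
#' \eqn{t = r\sqrt{(n-2-q)/(1-r^2)}} on \eqn{n-2-q} degrees of freedom
#' (q = number of covariates), two-sided. With no covariates this reduces
#' exactly to the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x q) or NULL.
#' @return list: r, p, statistic, df, n, nCovariates.
#' @export
partialPearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= q + 2) stop("need n > number of covariates + 2")
  if (q > 0) {
    Z <- cbind(1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) stop("rank-deficient covariate matrix")
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300))
    stop("constant vector after residualisation")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, statistic = tstat, df = df, n = n, nCovariates = q)
}

#' Mean metric value per atlas region
#'
#' @param metricVolume a \linkS4class{Volume} (e.g. an FA map).
#' @param atlas an \linkS4class{AtlasLabelMap} on the same grid.
#' @param labels region labels to extract (e.g. the top-5 weight regions).
#' @return named numeric vector of per-region means.
#' @export
extractRegionMeans <- function(metricVolume, atlas, labels) {
  lab <- atlasLabels(atlas)
  checkSameGrid(metricVolume, lab)
  lv <- volData(lab)
  mv <- volData(metricVolume)
  out <- vapply(labels, function(l) {
    sel <- lv == l
    if (!any(sel))
      stop(sprintf("region %d has no voxels", l))
    mean(mv[sel])
  }, numeric(1))
  names(out) <- regionNames(atlas)[as.character(labels)]
  out
}

#' Per-subject regional diffusion profiles
#'
#' For each subject, the mean of one diffusion metric over each of the given
#' regions -- the design matrix of \code{\link{multivariateRegression}}.
#'
#' @param cohort a \linkS4class{Cohort} with diffusion channels.
#' @param metric one of "fa", "md", "ad", "rd".
#' @param labels region labels (typically \code{\link{topRegions}} output).
#' @return subjects x regions matrix.
#' @export
regionMetricProfiles <- function(cohort, metric, labels) {
  subs <- cohortSubjects(cohort)
  atlas <- cohortAtlas(cohort)
  out <- t(vapply(subs, function(s)
    extractRegionMeans(channel(s, metric), atlas, labels),
    numeric(length(labels))))
  rownames(out) <- vapply(subs, subjectId, character(1))
  out
}

#' Multiple linear regression of one score on regional metric means
#'
#' Ordinary least squares of the score on an intercept plus the k region
#' means, reported through the overall F statistic
#' \eqn{F = (SSR/k)/(SSE/(n-k-1))} and its F-distribution p-value (one F
#' per score/metric pair). With covariates supplied, the model additionally
#' adjusts for them and F becomes the partial F of the region block. A
#' perfect fit (SSE = 0) reports F = Inf, p = 0.
#'
#' @param scores numeric response (length n).
#' @param profiles n x k matrix of region means.
#' @param covariates optional n x q matrix of adjustment covariates.
#' @return list: F, p, dfModel, dfResid, coefficients, r2.
#' @export
multivariateRegression <- function(scores, profiles, covariates = NULL) {
  y <- as.numeric(scores)
  Xr <- as.matrix(profiles)
  n <- length(y)
  k <- ncol(Xr)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + q + 1) stop("need n > number of predictors + 1")
  X0 <- if (q > 0) cbind(1, as.matrix(covariates)) else
    matrix(1, nrow = n, ncol = 1)
  X1 <- cbind(X0, Xr)
  if (qr(X1)$rank < ncol(X1)) stop("collinear design matrix")
  fit1 <- stats::lm.fit(X1, y)
  fit0 <- stats::lm.fit(X0, y)
  sse1 <- sum(fit1$residuals^2)
  sse0 <- sum(fit0$residuals^2)
  dfResid <- n - ncol(X1)
  sst <- sum((y - mean(y))^2)
  if (sse1 <= 1e-12 * max(sst, 1)) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- ((sse0 - sse1) / k) / (sse1 / dfResid)
    p <- pf(Fv, k, dfResid, lower.tail = FALSE)
  }
  coefs <- fit1$coefficients
  names(coefs) <- c("(Intercept)",
                    if (q > 0) paste0("cov", seq_len(q)),
                    colnames(Xr) %||% paste0("region", seq_len(k)))
  list(F = Fv, p = p, dfModel = k, dfResid = dfResid,
       coefficients = coefs, r2 = 1 - sse1 / sst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
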