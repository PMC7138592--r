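#' VoxelWeightMap: voxel-space weights of a fitted linear-kernel RVR
#'
#' @slot weights \linkS4class{Volume}; zero outside the analysis mask.
#' @slot testName the score the model predicts.
#' @slot foldId fold index, or "all".
#' @export
setClass("VoxelWeightMap",
  representation(weights = "Volume", testName = "character",
                 foldId = "character"))

#' @rdname VoxelWeightMap-class
#' @param x a VoxelWeightMap.
#' @export
weightVolume <- function(x) x@weights

setMethod("show", "VoxelWeightMap", function(object) {
  cat(sprintf("VoxelWeightMap [%s, fold %s]\n", object@testName,
              object@foldId))
})

#' Control parameters for fitRVR
#'
#' @param maxIterations cap on hyperparameter re-estimation sweeps.
#' @param tol convergence tolerance on max |change in log alpha|.
#' @param pruneThreshold basis i is pruned when alpha_i exceeds this.
#' @param biasAlpha fixed precision of the bias basis; small, so the bias
#'   carries a large prior variance and is effectively unpenalised.
#' @param fixedAlpha if non-NULL, every precision (bias included) is frozen
#'   at this common value and never updated -- the ridge-regression limit.
#' @param fixedSigma2 if non-NULL, the noise variance is frozen.
#' @param sigma2Floor lower bound keeping the noise variance positive on
#'   noise-free targets.
#' @param evidenceTol optional early-stopping tolerance on the change of the
#'   log marginal likelihood: when set, iteration stops once the evidence
#'   improves by less than this (useful in permutation loops where only the
#'   fitted predictions matter; precisions still marching towards the prune
#'   threshold then remain as low-weight relevance vectors). NULL (default)
#'   iterates to the alpha-based criterion.
#' @return list of class "rvrControl".
#' @export
rvrControl <- function(maxIterations = 500L, tol = 1e-3,
                       pruneThreshold = 1e9, biasAlpha = 1e-6,
                       fixedAlpha = NULL, fixedSigma2 = NULL,
                       sigma2Floor = 1e-10, evidenceTol = NULL) {
  structure(list(maxIterations = as.integer(maxIterations), tol = tol,
                 pruneThreshold = pruneThreshold, biasAlpha = biasAlpha,
                 fixedAlpha = fixedAlpha, fixedSigma2 = fixedSigma2,
                 sigma2Floor = sigma2Floor, evidenceTol = evidenceTol),
            class = "rvrControl")
}

# Cholesky with a diagonal jitter fallback for near-singular posteriors.
cholSafe <- function(B) {
  out <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(out)) {
    jit <- 1e-8 * mean(diag(B))
    out <- chol(B + diag(jit, nrow(B)))
  }
  out
}

#' Fit a relevance vector regression
#'
#' Sparse Bayesian linear regression with a linear kernel (Tipping-style
#' type-II maximum likelihood). The design is \eqn{\Phi = [K, 1]} with
#' \eqn{K_{ij} = x_i \cdot x_j}; each weight has a zero-mean Gaussian prior
#' with its own precision \eqn{\alpha_i}. Each sweep computes the posterior
#' \eqn{\Sigma = (\sigma^{-2}\Phi^T\Phi + A)^{-1}},
#' \eqn{\mu = \sigma^{-2}\Sigma\Phi^T y}, then re-estimates
#' \eqn{\alpha_i \leftarrow \gamma_i/\mu_i^2} with
#' \eqn{\gamma_i = 1 - \alpha_i \Sigma_{ii}} and
#' \eqn{\sigma^2 \leftarrow \|y-\Phi\mu\|^2/(N-\sum\gamma)}, pruning bases
#' whose precision diverges. The surviving kernel bases index the relevance
#' vectors. Fully deterministic: fixed initialisation
#' (\eqn{\alpha_i = 1/N^2}, \eqn{\sigma^2 = 0.1 var(y)}), no randomness.
#'
#' @param X subjects x features matrix, or NULL when \code{gram} is given.
#' @param y numeric response, length N >= 3, non-constant.
#' @param control see \code{\link{rvrControl}}.
#' @param gram optional precomputed N x N linear-kernel Gram matrix
#'   (\code{tcrossprod(X)}); when fitted this way the state holds no feature
#'   rows and \code{\link{predictRVR}} needs kernel columns instead.
#' @return An \linkS4class{RVRState}; slot \code{logMarginal} traces the
#'   (non-decreasing) log marginal likelihood across iterations.
#' @export
fitRVR <- function(X = NULL, y, control = rvrControl(), gram = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  if (N < 3L) stop("need at least 3 samples")
  if (!all(is.finite(y))) stop("y must be finite")
  if (var(y) == 0) stop("y is constant; regression scale undefined")
  if (is.null(gram)) {
    if (is.null(X)) stop("provide X or gram")
    X <- as.matrix(X)
    if (!all(is.finite(X))) stop("X must be finite")
    gram <- tcrossprod(X)
  }
  stopifnot(nrow(gram) == N, ncol(gram) == N)
  core <- .rvr_core(gram, y, control)
  rvFeat <- if (!is.null(X)) X[core$relIdx, , drop = FALSE] else
    matrix(numeric(0), nrow = 0, ncol = 0)
  new("RVRState", relevanceIndices = as.integer(core$relIdx), mu = core$mu,
      alpha = core$alpha, sigma2 = core$sigma2, kernel = "linear",
      rvFeatures = rvFeat, converged = core$converged,
      nIterations = core$it, logMarginal = core$logml)
}

# hyperparameter loop on a precomputed Gram; returns a plain list (the S4
# wrapping and input checks live in fitRVR)
.rvr_core <- function(gram, y, control) {
  N <- length(y)
  # Condition the basis: the alpha initialisation and prune threshold assume
  # an O(1) basis scale, while a raw dot-product Gram scales with the number
  # of feature voxels. Fitting on gram/s and dividing the kernel weights by
  # s afterwards is exactly equivalent (w ~ N(0, 1/alpha) absorbs the
  # rescaling) and keeps the hyperparameter dynamics well-behaved. The
  # frozen-alpha (ridge) limit is defined on the raw basis, so it skips
  # this.
  s <- if (is.null(control$fixedAlpha)) mean(diag(gram)) else 1
  if (!is.finite(s) || s <= 0) s <- 1
  Phi <- cbind(gram / s, 1)
  M <- N + 1L
  bias <- M
  PtP <- crossprod(Phi)
  Pty <- drop(crossprod(Phi, y))
  yty <- sum(y^2)

  alpha <- rep(1 / N^2, M)
  alpha[bias] <- control$biasAlpha
  sigma2 <- 0.1 * var(y)
  if (!is.null(control$fixedAlpha)) alpha <- rep(control$fixedAlpha, M)
  if (!is.null(control$fixedSigma2)) sigma2 <- control$fixedSigma2
  frozen <- !is.null(control$fixedAlpha)

  active <- rep(TRUE, M)
  logml <- numeric(0)
  converged <- FALSE
  it <- 0L
  mu <- NULL

  posterior <- function(act, alph, s2) {
    B <- PtP[act, act, drop = FALSE] / s2
    diag(B) <- diag(B) + alph[act]
    R <- cholSafe(B)
    Sigma <- chol2inv(R)
    mu <- drop(Sigma %*% Pty[act]) / s2
    list(Sigma = Sigma, mu = mu, logdetB = 2 * sum(log(diag(R))))
  }

  while (it < control$maxIterations) {
    it <- it + 1L
    pos <- posterior(active, alpha, sigma2)
    mu <- pos$mu
    a <- alpha[active]
    gamma <- 1 - a * diag(pos$Sigma)
    quad <- (yty - sum(Pty[active] * mu)) / sigma2
    L <- -0.5 * (N * log(2 * pi) + N * log(sigma2) - sum(log(a)) +
                   pos$logdetB + quad)
    logml <- c(logml, L)
    if (frozen && !is.null(control$fixedSigma2)) { converged <- TRUE; break }
    if (!is.null(control$evidenceTol) && it > 1L &&
        L - logml[it - 1L] < control$evidenceTol) { converged <- TRUE; break }

    actIdx <- which(active)
    kern <- actIdx[actIdx != bias]
    newAlpha <- alpha
    if (!frozen) {
      pos_k <- match(kern, actIdx)
      gk <- gamma[pos_k]
      mk <- mu[pos_k]
      na <- pmax(gk, 0) / (mk * mk)
      na[!is.finite(na) | na <= 0] <- Inf
      newAlpha[kern] <- na
    }
    if (is.null(control$fixedSigma2)) {
      # the ML noise update sigma2 = ||resid||^2 / (N - sum gamma) is only
      # meaningful when the effective degrees of freedom leave slack; while
      # the (over-complete) basis still interpolates, keep the previous
      # sigma2 so alpha-driven pruning can act from a regularised posterior
      resid <- y - drop(Phi[, active, drop = FALSE] %*% mu)
      denom <- N - sum(gamma)
      if (denom > 0.5)
        sigma2 <- max(sum(resid^2) / denom, control$sigma2Floor * var(y))
    }
    keep <- newAlpha[kern] <= control$pruneThreshold
    survivors <- kern[keep]
    delta <- if (length(survivors))
      max(abs(log(newAlpha[survivors]) - log(alpha[survivors]))) else 0
    active[kern[!keep]] <- FALSE
    alpha[kern] <- newAlpha[kern]
    if (delta < control$tol) { converged <- TRUE; break }
  }

  pos <- posterior(active, alpha, sigma2)
  actIdx <- which(active)
  relIdx <- actIdx[actIdx != bias]
  ord <- c(relIdx, bias)
  muFull <- pos$mu[match(ord, actIdx)]
  nk <- length(relIdx)
  if (nk > 0L) muFull[seq_len(nk)] <- muFull[seq_len(nk)] / s
  list(relIdx = relIdx, mu = muFull, alpha = alpha[ord], sigma2 = sigma2,
       converged = converged, it = it, logml = logml)
}

# kernel-column prediction from a core-fit list
.rvr_core_predict <- function(core, Knew) {
  nrv <- length(core$relIdx)
  muB <- core$mu[nrv + 1L]
  if (nrv == 0L) return(rep(muB, nrow(Knew)))
  drop(Knew[, core$relIdx, drop = FALSE] %*% core$mu[seq_len(nrv)]) + muB
}

#' Predict from a fitted RVR
#'
#' \eqn{f(x) = \sum_{n \in RV} \mu_n (x \cdot x_n) + \mu_{bias}}.
#'
#' @param state an \linkS4class{RVRState} fitted from an explicit feature
#'   matrix (so it carries its relevance-vector features).
#' @param Xnew matrix of new samples (columns must match training features).
#' @return numeric predictions.
#' @export
predictRVR <- function(state, Xnew) {
  Xnew <- as.matrix(Xnew)
  nrv <- length(state@relevanceIndices)
  muB <- state@mu[nrv + 1L]
  if (nrv == 0L) return(rep(muB, nrow(Xnew)))
  if (nrow(state@rvFeatures) != nrv)
    stop("state carries no relevance-vector features; fit with X, not gram")
  if (ncol(Xnew) != ncol(state@rvFeatures))
    stop("feature dimension mismatch")
  drop(Xnew %*% crossprod(state@rvFeatures, state@mu[seq_len(nrv)])) + muB
}

# predict from kernel columns K[new, train] (full training order)
predictRVRKernel <- function(state, Knew) {
  nrv <- length(state@relevanceIndices)
  muB <- state@mu[nrv + 1L]
  if (nrv == 0L) return(rep(muB, nrow(Knew)))
  drop(Knew[, state@relevanceIndices, drop = FALSE] %*%
         state@mu[seq_len(nrv)]) + muB
}

#' Back-project a linear-kernel RVR onto voxel space
#'
#' For the linear kernel the fitted function is exactly a voxel-space linear
#' predictor: \eqn{w_{vox} = \sum_{n \in RV} \mu_n x_n} and
#' \eqn{f(x) = x \cdot w_{vox} + \mu_{bias}}. The weight vector is embedded
#' into the analysis mask as a Volume (zero outside).
#'
#' @param state an \linkS4class{RVRState} carrying relevance-vector
#'   features whose columns correspond to the in-mask voxels.
#' @param analysisMask binary \linkS4class{Volume} with as many 1-voxels as
#'   feature columns.
#' @param testName,foldId metadata attached to the map.
#' @return A \linkS4class{VoxelWeightMap}.
#' @export
backprojectWeights <- function(state, analysisMask, testName = "score",
                               foldId = "all") {
  if (!identical(state@kernel, "linear"))
    stop("back-projection is only defined for the linear kernel")
  idx <- which(volData(analysisMask) == 1)
  nrv <- length(state@relevanceIndices)
  arr <- array(0, dim(analysisMask))
  if (nrv > 0L) {
    if (ncol(state@rvFeatures) != length(idx))
      stop("analysis mask size does not match the feature dimension")
    w <- drop(crossprod(state@rvFeatures, state@mu[seq_len(nrv)]))
    arr[idx] <- w
  }
  new("VoxelWeightMap",
      weights = Volume(arr, voxelSize(analysisMask),
                       analysisMask@spaceTag),
      testName = testName, foldId = as.character(foldId))
}
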