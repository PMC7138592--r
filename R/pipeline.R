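#' Prediction accuracy metrics
#'
#' The three evaluation metrics used throughout the pipeline:
#' \itemize{
#' \item \code{computeCorr}: Pearson correlation between observed and
#'   predicted scores,
#'   \eqn{\sum_n (y_n-\mu_y)(f(x_n)-\mu_f) / \sqrt{\sum (y_n-\mu_y)^2
#'   \sum (f(x_n)-\mu_f)^2}}.
#' \item \code{computeMse}: \eqn{(1/N)\sum_n (y_n - f(x_n))^2}.
#' \item \code{computeNormMse}: MSE divided by the observed score range
#'   \eqn{y_{max}-y_{min}}, removing the effect of the score scale.
#' }
#'
#' @param yObs observed scores.
#' @param yPred predicted scores.
#' @return scalar.
#' @export
computeCorr <- function(yObs, yPred) {
  stopifnot(length(yObs) == length(yPred), length(yObs) >= 2)
  if (sd(yObs) == 0 || sd(yPred) == 0)
    stop("correlation undefined for a constant vector")
  dy <- yObs - mean(yObs)
  df_ <- yPred - mean(yPred)
  sum(dy * df_) / sqrt(sum(dy^2) * sum(df_^2))
}

#' @rdname computeCorr
#' @export
computeMse <- function(yObs, yPred) {
  stopifnot(length(yObs) == length(yPred))
  mean((yObs - yPred)^2)
}

#' @rdname computeCorr
#' @export
computeNormMse <- function(yObs, yPred) {
  rng <- max(yObs) - min(yObs)
  if (rng == 0) stop("norm MSE undefined when y_max equals y_min")
  computeMse(yObs, yPred) / rng
}

#' PredictionResult: pooled out-of-fold predictions for one score
#'
#' @slot testName score name.
#' @slot yObs,yPred observed and out-of-fold predicted scores, subject order.
#' @slot foldAssignment fold id per subject; each subject is predicted
#'   exactly once, by the model that excluded it.
#' @slot corr,mse,normMse metrics on the pooled predictions (corr is NA if
#'   the pooled predictions are constant).
#' @slot perFoldStates list of \linkS4class{RVRState}, one per fold (empty
#'   when states were not kept).
#' @slot trainIndices per-fold training-subject indices (parallel to
#'   perFoldStates; relevance indices in each state refer to this order).
#' @export
setClass("PredictionResult",
  representation(testName = "character", yObs = "numeric", yPred = "numeric",
                 foldAssignment = "integer", corr = "numeric",
                 mse = "numeric", normMse = "numeric",
                 perFoldStates = "list", trainIndices = "list"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (length(object@yObs) != length(object@yPred))
    msg <- c(msg, "yObs and yPred must have equal length")
  if (!is.na(object@corr) && abs(object@corr) > 1 + 1e-12)
    msg <- c(msg, "corr must lie in [-1, 1]")
  if (object@mse < 0) msg <- c(msg, "mse must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult [%s]: N=%d, CORR=%.3f, MSE=%.3f, norm MSE=%.3f\n",
              object@testName, length(object@yObs), object@corr,
              object@mse, object@normMse))
})

#' @rdname PredictionResult-class
#' @param x a PredictionResult.
#' @export
predictionMetrics <- function(x)
  c(corr = x@corr, mse = x@mse, norm_mse = x@normMse)

#' Cross-validated RVR prediction of one score
#'
#' Subjects are partitioned into near-equal folds (sizes differ by at most
#' one) by a seeded shuffle; for each fold an RVR is fitted on the
#' complement and predicts the held-out subjects. Metrics are computed on
#' the pooled out-of-fold predictions.
#'
#' @param X subjects x voxel feature matrix (rows ordered as \code{y}).
#' @param y score vector.
#' @param nFolds number of folds (7 by default).
#' @param seed seed for the fold shuffle.
#' @param control RVR control, see \code{\link{rvrControl}}.
#' @param gram optional precomputed \code{tcrossprod(X)}; X may then be NULL
#'   (per-fold states then carry no feature rows).
#' @param keepStates keep per-fold RVRStates for weight back-projection.
#' @param testName label carried into the result.
#' @return A \linkS4class{PredictionResult}.
#' @export
crossvalPredict <- function(X = NULL, y, nFolds = 7L, seed = 1L,
                            control = rvrControl(), gram = NULL,
                            keepStates = TRUE, testName = "score") {
  y <- as.numeric(y)
  N <- length(y)
  stopifnot(N >= nFolds, nFolds >= 2L)
  if (is.null(gram)) {
    if (is.null(X)) stop("provide X or gram")
    X <- as.matrix(X)
    gram <- tcrossprod(X)
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(nFolds), N)))
  yPred <- numeric(N)
  states <- vector("list", if (keepStates) nFolds else 0L)
  trainIdx <- vector("list", if (keepStates) nFolds else 0L)
  for (f in seq_len(nFolds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    core <- .rvr_core(gram[tr, tr, drop = FALSE], y[tr], control)
    yPred[te] <- .rvr_core_predict(core, gram[te, tr, drop = FALSE])
    if (keepStates) {
      rvFeat <- if (!is.null(X)) X[tr[core$relIdx], , drop = FALSE] else
        matrix(numeric(0), nrow = 0, ncol = 0)
      states[[f]] <- new("RVRState",
                         relevanceIndices = as.integer(core$relIdx),
                         mu = core$mu, alpha = core$alpha,
                         sigma2 = core$sigma2, kernel = "linear",
                         rvFeatures = rvFeat, converged = core$converged,
                         nIterations = core$it, logMarginal = core$logml)
      trainIdx[[f]] <- tr
    }
  }
  corr <- if (sd(yPred) == 0 || sd(y) == 0) NA_real_ else
    computeCorr(y, yPred)
  new("PredictionResult", testName = testName, yObs = y, yPred = yPred,
      foldAssignment = as.integer(fold), corr = corr,
      mse = computeMse(y, yPred),
      normMse = if (max(y) > min(y)) computeNormMse(y, yPred) else NA_real_,
      perFoldStates = states, trainIndices = trainIdx)
}

#' PermutationResult: permutation-based significance of a CV prediction
#'
#' @slot testName score name.
#' @slot nPermutations permutations run.
#' @slot observed named metrics of the unpermuted model.
#' @slot nullCorr,nullMse,nullNormMse null distributions (length
#'   nPermutations; NA where a permutation produced constant predictions).
#' @slot pValues add-one permutation p-values: high CORR and low MSE /
#'   norm MSE count as extreme.
#' @export
setClass("PermutationResult",
  representation(testName = "character", nPermutations = "integer",
                 observed = "numeric", nullCorr = "numeric",
                 nullMse = "numeric", nullNormMse = "numeric",
                 pValues = "numeric"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (any(object@pValues <= 0 | object@pValues > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(object@nullCorr) != object@nPermutations)
    msg <- c(msg, "null vectors must have length nPermutations")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult [%s]: %d permutations; p(CORR)=%.4f, p(MSE)=%.4f, p(norm MSE)=%.4f\n",
              object@testName, object@nPermutations,
              object@pValues["corr"], object@pValues["mse"],
              object@pValues["norm_mse"]))
})

#' Permutation test of a cross-validated prediction
#'
#' The scores are randomly shuffled and the entire cross-validation loop is
#' re-run (the model is retrained) for each permutation, keeping the fold
#' partition scheme. One-sided add-one p-values:
#' \eqn{p_{CORR} = (1 + \#\{CORR_{null} \ge CORR_{obs}\})/(1 + B)}; for MSE
#' and norm MSE the tail is reversed (smaller is better). P-values are
#' therefore never smaller than \eqn{1/(B+1)}.
#'
#' @param X,y,nFolds,control,gram see \code{\link{crossvalPredict}}.
#' @param nPermutations number of retrainings (the reference analysis used
#'   1000).
#' @param seed seeds both the fold shuffle and the permutation stream.
#' @param testName label carried through.
#' @return A \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(X = NULL, y, nFolds = 7L, nPermutations = 1000L,
                            seed = 1L, control = rvrControl(), gram = NULL,
                            testName = "score") {
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  if (is.null(gram)) {
    if (is.null(X)) stop("provide X or gram")
    X <- as.matrix(X)
    gram <- tcrossprod(X)
  }
  obs <- crossvalPredict(X = NULL, y = y, nFolds = nFolds, seed = seed,
                         control = control, gram = gram,
                         keepStates = FALSE, testName = testName)
  perms <- with_seed(seed + 104729L, {
    lapply(seq_len(nPermutations), function(b) sample(length(y)))
  })
  fold <- with_seed(seed, sample(rep_len(seq_len(nFolds), length(y))))
  nullm <- vapply(perms, function(pm) {
    .cv_metrics(gram, y[pm], fold, nFolds, control)
  }, numeric(3))
  nullCorr <- nullm[1, ]; nullMse <- nullm[2, ]; nullNorm <- nullm[3, ]
  pv <- c(
    corr = (1 + sum(nullCorr >= obs@corr, na.rm = TRUE)) / (1 + nPermutations),
    mse = (1 + sum(nullMse <= obs@mse, na.rm = TRUE)) / (1 + nPermutations),
    norm_mse = (1 + sum(nullNorm <= obs@normMse, na.rm = TRUE)) /
      (1 + nPermutations))
  if (is.na(obs@corr)) pv["corr"] <- NA_real_
  new("PermutationResult", testName = testName,
      nPermutations = as.integer(nPermutations),
      observed = predictionMetrics(obs),
      nullCorr = nullCorr, nullMse = nullMse, nullNormMse = nullNorm,
      pValues = pv)
}

# lightweight CV metrics used inside the permutation loop: same folds and
# fits as crossvalPredict, no S4 construction
.cv_metrics <- function(gram, y, fold, nFolds, control) {
  yPred <- numeric(length(y))
  for (f in seq_len(nFolds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    core <- .rvr_core(gram[tr, tr, drop = FALSE], y[tr], control)
    yPred[te] <- .rvr_core_predict(core, gram[te, tr, drop = FALSE])
  }
  corr <- if (sd(yPred) == 0) NA_real_ else computeCorr(y, yPred)
  mse <- computeMse(y, yPred)
  nmse <- if (max(y) > min(y)) mse / (max(y) - min(y)) else NA_real_
  c(corr, mse, nmse)
}

#' Lesion-map feature matrix for a cohort
#'
#' Stacks each subject's lesion probability map (thresholded, as produced by
#' the segmenter, or the ground-truth mask) over the analysis-mask voxels
#' into the subjects x voxels matrix the RVR consumes.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param maps optional named list of \linkS4class{Volume}s per subject
#'   (e.g. thresholded probability maps); defaults to the subjects' true
#'   lesion masks.
#' @return list: \code{X} (subjects x voxels), \code{mask} (the analysis
#'   mask Volume), \code{subjectIds}.
#' @export
lesionFeatureMatrix <- function(cohort, maps = NULL) {
  am <- analysisMask(cohort)
  idx <- which(volData(am) == 1)
  subs <- cohortSubjects(cohort)
  ids <- vapply(subs, subjectId, character(1))
  if (is.null(maps)) {
    maps <- lapply(subs, trueLesionMask)
    names(maps) <- ids
  }
  X <- t(vapply(ids, function(id) {
    v <- maps[[id]]
    checkSameGrid(v, am)
    volData(v)[idx]
  }, numeric(length(idx))))
  rownames(X) <- ids
  list(X = X, mask = am, subjectIds = ids)
}
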