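#' KNNConfig: parameters of the KNN lesion segmenter
#'
#' @slot k neighbour count. With the fixed 2000-point lesion budget pooled
#'   over ten training subjects, the local density of lesion training points
#'   supports only small neighbourhoods once a strict high probability
#'   threshold is applied (a voxel needs essentially all k nearest points to
#'   be lesion-labelled to exceed 0.9); the default k = 5 reflects that
#'   density.
#' @slot spatialWeighting scalar multiplier applied to the mm coordinate
#'   features (1 reproduces the published configuration; 0 gives a pure
#'   intensity classifier).
#' @slot featureChannels ordered channel names used as intensity features.
#' @slot nLesionPoints,nNonLesionPoints training-point budget of the
#'   fixed + unbalanced sampling policy (2000 / 10000 by default).
#' @slot probabilityThreshold probability threshold; voxels whose
#'   probability strictly exceeds it are retained in the binary mask.
#' @export
setClass("KNNConfig",
  representation(k = "integer", spatialWeighting = "numeric",
                 featureChannels = "character", nLesionPoints = "integer",
                 nNonLesionPoints = "integer",
                 probabilityThreshold = "numeric"))

setValidity("KNNConfig", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@spatialWeighting < 0) msg <- c(msg, "spatialWeighting must be >= 0")
  if (object@probabilityThreshold < 0 || object@probabilityThreshold > 1)
    msg <- c(msg, "probabilityThreshold must lie in [0,1]")
  if (object@nLesionPoints < 1L || object@nNonLesionPoints < 1L)
    msg <- c(msg, "training point budgets must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname KNNConfig-class
#' @param k,spatialWeighting,featureChannels,nLesionPoints,nNonLesionPoints,probabilityThreshold
#'   see slots.
#' @export
knnConfig <- function(k = 5L, spatialWeighting = 1,
                      featureChannels = c("t1", "flair"),
                      nLesionPoints = 2000L, nNonLesionPoints = 10000L,
                      probabilityThreshold = 0.9) {
  new("KNNConfig", k = as.integer(k), spatialWeighting = spatialWeighting,
      featureChannels = featureChannels,
      nLesionPoints = as.integer(nLesionPoints),
      nNonLesionPoints = as.integer(nNonLesionPoints),
      probabilityThreshold = probabilityThreshold)
}

#' TrainingPointSet: sampled labelled voxels for the KNN classifier
#'
#' @slot features points x feature-dim matrix (z-scored intensities followed
#'   by weighted mm coordinates).
#' @slot labels integer 0/1 vector, 1 = lesion.
#' @slot provenance data.frame (subject_id, voxel linear index) per point.
#' @export
setClass("TrainingPointSet",
  representation(features = "matrix", labels = "integer",
                 provenance = "data.frame"))

setValidity("TrainingPointSet", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "features rows and labels length must match")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrainingPointSet", function(object) {
  cat(sprintf("TrainingPointSet: %d lesion + %d non-lesion points, %d features\n",
              sum(object@labels == 1L), sum(object@labels == 0L),
              ncol(object@features)))
})

# z-score with the population-SD convention (divide by n, not n-1); a
# constant vector maps to all zeros.
zscorePop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

#' Extract KNN features for the in-mask voxels of a subject
#'
#' Per voxel: each configured channel intensity z-scored within the brain
#' mask (population-SD convention, per subject), followed by the three
#' voxel-center coordinates in mm, each multiplied by the spatial weighting.
#' Z-scoring makes segmentation invariant to affine rescaling of a channel
#' and puts intensities and mm coordinates on commensurate scales.
#'
#' @param subject a \linkS4class{SubjectRecord}.
#' @param cfg a \linkS4class{KNNConfig}.
#' @param brainMask binary \linkS4class{Volume}.
#' @return list: \code{voxelIndices} (1-based linear indices into the grid)
#'   and \code{features} (matrix, rows aligned with voxelIndices).
#' @export
extractFeatures <- function(subject, cfg, brainMask) {
  miss <- setdiff(cfg@featureChannels, names(subject@channels))
  if (length(miss))
    stop(sprintf("subject %s is missing channel(s): %s",
                 subjectId(subject), paste(miss, collapse = ", ")))
  mask <- volData(brainMask) == 1
  idx <- which(mask)
  chans <- lapply(cfg@featureChannels, function(ch) {
    v <- channel(subject, ch)
    checkSameGrid(v, brainMask)
    zscorePop(volData(v)[idx])
  })
  ctr <- voxelCentersMm(dim(brainMask), voxelSize(brainMask))
  sp <- ctr[idx, , drop = FALSE] * cfg@spatialWeighting
  feat <- cbind(do.call(cbind, chans), sp)
  colnames(feat) <- c(cfg@featureChannels, "x_mm", "y_mm", "z_mm")
  list(voxelIndices = idx, features = feat)
}

#' Build the KNN training set from labelled subjects
#'
#' Fixed + unbalanced sampling policy: lesion points drawn uniformly without
#' replacement from mask=1 voxels pooled across the labelled subjects,
#' non-lesion points from any in-brain mask=0 voxel. When a class has fewer
#' eligible voxels than its budget, all of them are used and a warning is
#' raised. Deterministic given \code{seed}.
#'
#' @param subjects list of \linkS4class{SubjectRecord}s with lesion masks
#'   (the "manually labelled" training subjects).
#' @param cfg a \linkS4class{KNNConfig}.
#' @param brainMask binary \linkS4class{Volume}.
#' @param seed integer seed.
#' @return A \linkS4class{TrainingPointSet}.
#' @export
buildTrainingSet <- function(subjects, cfg, brainMask, seed = 1L) {
  stopifnot(length(subjects) >= 1L)
  feats <- list(); labs <- list(); prov <- list()
  for (s in subjects) {
    if (is.null(trueLesionMask(s)))
      stop(sprintf("subject %s has no lesion mask", subjectId(s)))
    ex <- extractFeatures(s, cfg, brainMask)
    m <- volData(trueLesionMask(s))[ex$voxelIndices]
    feats[[length(feats) + 1L]] <- ex$features
    labs[[length(labs) + 1L]] <- as.integer(m == 1)
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = subjectId(s), voxel = ex$voxelIndices,
      stringsAsFactors = FALSE)
  }
  feat <- do.call(rbind, feats)
  lab <- do.call(c, labs)
  prov <- do.call(rbind, prov)
  les_pool <- which(lab == 1L)
  non_pool <- which(lab == 0L)
  if (length(les_pool) == 0L)
    stop("no lesion voxels available in the training subjects")
  takePool <- function(pool, want, what) {
    if (length(pool) <= want) {
      if (length(pool) < want)
        warning(sprintf("only %d %s voxels available (requested %d); using all",
                        length(pool), what, want))
      pool
    } else sample(pool, want)
  }
  sel <- with_seed(seed, {
    c(takePool(les_pool, cfg@nLesionPoints, "lesion"),
      takePool(non_pool, cfg@nNonLesionPoints, "non-lesion"))
  })
  new("TrainingPointSet", features = feat[sel, , drop = FALSE],
      labels = lab[sel], provenance = prov[sel, ])
}

#' KNN lesion probability
#'
#' For each query row, the fraction of lesion-labelled points among its k
#' nearest training points by Euclidean distance. Distance ties are broken
#' in favour of the lower training-point index, making the output
#' deterministic. Probabilities are exact multiples of 1/k.
#'
#' @param query matrix of query features.
#' @param train a \linkS4class{TrainingPointSet}.
#' @param k neighbour count, at most the number of training points.
#' @return numeric vector of probabilities in [0,1].
#' @export
knnProbability <- function(query, train, k) {
  stopifnot(is(train, "TrainingPointSet"))
  if (k > nrow(train@features))
    stop("k exceeds the number of training points")
  .knn_prob_cpp(train@features, train@labels,
                as.matrix(query), as.integer(k))
}

#' Segment one subject's lesions
#'
#' Computes the lesion probability map over the brain mask (0 outside),
#' applies the strict probability threshold, and reports the lesion volume
#' in ml.
#'
#' @param subject a \linkS4class{SubjectRecord}.
#' @param train a \linkS4class{TrainingPointSet}.
#' @param cfg a \linkS4class{KNNConfig}.
#' @param brainMask binary \linkS4class{Volume}.
#' @param threshold probability threshold in [0,1]; voxels with probability
#'   strictly above it form the lesion mask (so threshold 1 always yields an
#'   empty mask).
#' @return A \linkS4class{LesionSegmentation}.
#' @export
segmentSubject <- function(subject, train, cfg, brainMask,
                           threshold = cfg@probabilityThreshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ex <- extractFeatures(subject, cfg, brainMask)
  p <- knnProbability(ex$features, train, cfg@k)
  g <- dim(brainMask)
  prob <- array(0, g)
  prob[ex$voxelIndices] <- p
  mask <- array(as.numeric(prob > threshold), g)
  vs <- voxelSize(brainMask)
  new("LesionSegmentation",
      probabilityMap = Volume(prob, vs, brainMask@spaceTag),
      binaryMask = Volume(mask, vs, brainMask@spaceTag),
      volumeMl = sum(mask) * prod(vs) / 1000,
      threshold = threshold)
}

#' Dice overlap of two binary masks
#'
#' 2|A n B| / (|A| + |B|); defined as 1 when both masks are empty.
#'
#' @param a,b binary \linkS4class{Volume}s on one grid.
#' @return scalar in [0,1].
#' @export
dice <- function(a, b) {
  checkSameGrid(a, b)
  da <- volData(a); db <- volData(b)
  if (!all(da %in% c(0, 1)) || !all(db %in% c(0, 1)))
    stop("dice requires binary volumes")
  sa <- sum(da); sb <- sum(db)
  if (sa + sb == 0) return(1.0)
  2 * sum(da * db) / (sa + sb)
}
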