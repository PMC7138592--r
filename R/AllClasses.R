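#' @import methods
#' @importFrom stats cor lm pf pt quantile rbinom rnorm runif sd var
#' @importFrom utils read.delim head
#' @useDynLib WMLpredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volume: a 3D scalar image on a common grid
#'
#' The universal carrier for intensities, lesion probabilities, binary masks,
#' atlas labels, voxel weights and diffusion indices. All volumes entering a
#' joint operation must live on one grid (identical array dimensions and
#' voxel size); the pipeline performs no resampling.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize numeric(3), edge length of a voxel in mm along each axis.
#' @slot spaceTag free-text identifier of the common space the grid lives in.
#' @export
setClass("Volume",
  representation(data = "array", voxelSize = "numeric", spaceTag = "character"),
  prototype(voxelSize = c(1, 1, 1), spaceTag = "common"))

setValidity("Volume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 strictly positive values")
  if (length(object@spaceTag) != 1L)
    msg <- c(msg, "spaceTag must be a single string")
  if (length(msg)) msg else TRUE
})

setClassUnion("VolumeOrNULL", members = c("Volume", "NULL"))

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param voxelSize voxel edge lengths in mm (length 3, recycled from length 1).
#' @param spaceTag identifier of the common space.
#' @return A \linkS4class{Volume}.
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)), voxelSize = 2)
#' voxelVolume(v)  # 8 mm^3
#' @export
Volume <- function(data, voxelSize = c(1, 1, 1), spaceTag = "common") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("Volume", data = data, voxelSize = as.numeric(voxelSize),
      spaceTag = spaceTag)
}

#' @describeIn Volume Array dimensions of the grid.
#' @param x,object a Volume.
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' Accessors for Volume
#'
#' @param x a \linkS4class{Volume}.
#' @return \code{volData} the 3D array; \code{voxelSize} the mm edge lengths;
#'   \code{voxelVolume} the volume of one voxel in mm^3.
#' @export
volData <- function(x) x@data

#' @rdname volData
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname volData
#' @export
voxelVolume <- function(x) prod(x@voxelSize)

setMethod("show", "Volume", function(object) {
  cat(sprintf("Volume %s, voxel %s mm [%s]\n",
              paste(dim(object@data), collapse = "x"),
              paste(format(object@voxelSize, trim = TRUE), collapse = "x"),
              object@spaceTag))
})

#' Assert that volumes share one grid
#'
#' All volumes combined in any operation must have identical array dimensions
#' and voxel sizes; this is the enforcement point.
#'
#' @param ... Volumes to compare.
#' @return invisibly \code{TRUE}; errors on any mismatch.
#' @export
checkSameGrid <- function(...) {
  vols <- list(...)
  stopifnot(length(vols) >= 1L)
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!identical(dim(v@data), dim(ref@data)))
      stop("grid mismatch: volumes have different array dimensions")
    if (!isTRUE(all.equal(v@voxelSize, ref@voxelSize)))
      stop("grid mismatch: volumes have different voxel sizes")
  }
  invisible(TRUE)
}

#' AtlasLabelMap: integer-labelled parcellation of the common grid
#'
#' Mirrors a white-matter label atlas (such as the 48-region JHU atlas):
#' an integer label image (0 = background) plus per-label region names and
#' hemisphere assignments.
#'
#' @slot labels Volume whose data are nonnegative integer labels.
#' @slot regionNames named character vector, names are label integers.
#' @slot regionHemisphere named character vector in \{"L","R","none"\}.
#' @export
setClass("AtlasLabelMap",
  representation(labels = "Volume", regionNames = "character",
                 regionHemisphere = "character"))

setValidity("AtlasLabelMap", function(object) {
  msg <- character()
  lab <- object@labels@data
  if (any(lab < 0) || any(lab != round(lab)))
    msg <- c(msg, "labels must be nonnegative integers")
  present <- setdiff(unique(as.integer(lab)), 0L)
  if (!all(as.character(present) %in% names(object@regionNames)))
    msg <- c(msg, "every nonzero label must have an entry in regionNames")
  if (!all(object@regionHemisphere %in% c("L", "R", "none")))
    msg <- c(msg, "regionHemisphere entries must be L, R or none")
  if (length(msg)) msg else TRUE
})

#' @rdname AtlasLabelMap-class
#' @param labels,regionNames,regionHemisphere see slots.
#' @export
AtlasLabelMap <- function(labels, regionNames,
                          regionHemisphere = NULL) {
  if (is.null(regionHemisphere)) {
    regionHemisphere <- rep("none", length(regionNames))
    names(regionHemisphere) <- names(regionNames)
  }
  new("AtlasLabelMap", labels = labels, regionNames = regionNames,
      regionHemisphere = regionHemisphere)
}

#' @rdname AtlasLabelMap-class
#' @param x an AtlasLabelMap.
#' @export
atlasLabels <- function(x) x@labels

#' @rdname AtlasLabelMap-class
#' @export
regionNames <- function(x) x@regionNames

#' @rdname AtlasLabelMap-class
#' @export
regionHemisphere <- function(x) x@regionHemisphere

setMethod("show", "AtlasLabelMap", function(object) {
  cat(sprintf("AtlasLabelMap: %d regions on grid %s\n",
              length(object@regionNames),
              paste(dim(object@labels@data), collapse = "x")))
})

#' SubjectRecord: one subject's channels, scores and covariates
#'
#' @slot subjectId character scalar.
#' @slot channels named list of \linkS4class{Volume}s (t1, flair; optionally
#'   fa, md, ad, rd), all grid-compatible.
#' @slot scores named numeric vector, one entry per neuropsychological test;
#'   missing values are NA (a missing score drops the subject from that
#'   test's analysis only).
#' @slot covariates named list with age (years), sex ("F"/"M"),
#'   education (years).
#' @slot trueLesionMask optional binary Volume (synthetic ground truth or a
#'   manually drawn mask used for training).
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", channels = "list",
                 scores = "numeric", covariates = "list",
                 trueLesionMask = "VolumeOrNULL"),
  prototype(trueLesionMask = NULL))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@channels)) {
    if (is.null(names(object@channels)) || any(names(object@channels) == ""))
      msg <- c(msg, "channels must be a named list")
    dims <- lapply(object@channels, function(v) dim(v@data))
    if (length(unique(dims)) > 1L)
      msg <- c(msg, "all channels must share one grid")
  }
  if (!is.null(object@trueLesionMask)) {
    m <- object@trueLesionMask@data
    if (!all(m %in% c(0, 1)))
      msg <- c(msg, "trueLesionMask must be binary")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SubjectRecord-class
#' @param subjectId,channels,scores,covariates,trueLesionMask see slots.
#' @export
SubjectRecord <- function(subjectId, channels = list(), scores = numeric(),
                          covariates = list(), trueLesionMask = NULL) {
  new("SubjectRecord", subjectId = subjectId, channels = channels,
      scores = scores, covariates = covariates,
      trueLesionMask = trueLesionMask)
}

#' @rdname SubjectRecord-class
#' @param x a SubjectRecord.
#' @export
subjectId <- function(x) x@subjectId

#' @rdname SubjectRecord-class
#' @param name channel name, e.g. "flair".
#' @export
channel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("subject %s has no channel '%s'", x@subjectId, name))
  x@channels[[name]]
}

#' @rdname SubjectRecord-class
#' @export
scores <- function(x) x@scores

#' @rdname SubjectRecord-class
#' @export
covariates <- function(x) x@covariates

#' @rdname SubjectRecord-class
#' @export
trueLesionMask <- function(x) x@trueLesionMask

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: channels {%s}, %d scores%s\n",
              object@subjectId, paste(names(object@channels), collapse = ", "),
              length(object@scores),
              if (!is.null(object@trueLesionMask)) ", lesion truth" else ""))
})

#' Cohort: subjects plus shared atlas and exclusion mask
#'
#' @slot subjects list of \linkS4class{SubjectRecord}.
#' @slot atlas \linkS4class{AtlasLabelMap} on the common grid.
#' @slot exclusionMask binary Volume (1 = excluded from prediction features,
#'   emulating the cerebellum exclusion).
#' @slot brainMask binary Volume (1 = in-brain).
#' @slot spec the \linkS4class{PhantomSpec} that generated the cohort, or NULL
#'   for cohorts assembled from files.
#' @export
setClass("Cohort",
  representation(subjects = "list", atlas = "AtlasLabelMap",
                 exclusionMask = "Volume", brainMask = "Volume",
                 spec = "ANY"),
  prototype(spec = NULL))

setValidity("Cohort", function(object) {
  msg <- character()
  for (s in object@subjects) {
    if (!is(s, "SubjectRecord")) { msg <- c(msg, "subjects must be SubjectRecords"); break }
    if (!is.null(s@trueLesionMask)) {
      if (!identical(dim(s@trueLesionMask@data), dim(object@atlas@labels@data))) {
        msg <- c(msg, "subject lesion masks must be grid-compatible with the atlas")
        break
      }
    }
  }
  if (!all(object@exclusionMask@data %in% c(0, 1)))
    msg <- c(msg, "exclusionMask must be binary")
  if (!all(object@brainMask@data %in% c(0, 1)))
    msg <- c(msg, "brainMask must be binary")
  if (length(msg)) msg else TRUE
})

#' @rdname Cohort-class
#' @param x a Cohort.
#' @export
cohortSubjects <- function(x) x@subjects

#' @rdname Cohort-class
#' @export
cohortAtlas <- function(x) x@atlas

#' @rdname Cohort-class
#' @export
exclusionMask <- function(x) x@exclusionMask

#' @rdname Cohort-class
#' @export
brainMask <- function(x) x@brainMask

#' Analysis mask of a cohort: brain minus the exclusion region
#'
#' Voxels that enter the prediction features: in-brain voxels outside the
#' designated exclusion structure (cerebellum analogue).
#' @param x a Cohort.
#' @return binary \linkS4class{Volume}.
#' @export
analysisMask <- function(x) {
  Volume(array(as.numeric(x@brainMask@data == 1 & x@exclusionMask@data == 0),
               dim(x@brainMask@data)),
         voxelSize = x@brainMask@voxelSize, spaceTag = x@brainMask@spaceTag)
}

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects, %d atlas regions, grid %s\n",
              length(object@subjects), length(object@atlas@regionNames),
              paste(dim(object@atlas@labels@data), collapse = "x")))
})

#' RVRState: a fitted relevance vector regression model
#'
#' Sparse Bayesian linear-kernel regression fitted by type-II maximum
#' likelihood. Basis functions are the kernel columns of the training
#' samples plus an effectively unpenalised bias; samples whose weight
#' survives hyperparameter-driven pruning are the relevance vectors.
#'
#' @slot relevanceIndices integer indices (into the training sample order)
#'   of the retained kernel bases.
#' @slot mu posterior mean weights for retained bases; the last entry is the
#'   bias weight.
#' @slot alpha per-weight precision hyperparameters matching \code{mu}.
#' @slot sigma2 noise variance.
#' @slot kernel kernel name; only "linear" is supported.
#' @slot rvFeatures feature rows (relevance vectors x voxels) when the model
#'   was fitted from an explicit feature matrix; a 0-row matrix when fitted
#'   from a precomputed Gram matrix.
#' @slot converged logical.
#' @slot nIterations iterations run.
#' @slot logMarginal per-iteration log marginal likelihood trace.
#' @export
setClass("RVRState",
  representation(relevanceIndices = "integer", mu = "numeric",
                 alpha = "numeric", sigma2 = "numeric", kernel = "character",
                 rvFeatures = "matrix", converged = "logical",
                 nIterations = "integer", logMarginal = "numeric"))

setValidity("RVRState", function(object) {
  msg <- character()
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha entries must be positive")
  if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be positive")
  if (length(object@mu) != length(object@relevanceIndices) + 1L)
    msg <- c(msg, "mu must hold one weight per relevance vector plus the bias")
  if (!identical(object@kernel, "linear"))
    msg <- c(msg, "only the linear kernel is supported")
  if (length(msg)) msg else TRUE
})

#' @rdname RVRState-class
#' @param x an RVRState.
#' @export
relevanceVectors <- function(x) x@relevanceIndices

#' @rdname RVRState-class
#' @export
posteriorMean <- function(x) x@mu

#' @rdname RVRState-class
#' @export
noiseVariance <- function(x) x@sigma2

setMethod("show", "RVRState", function(object) {
  cat(sprintf("RVRState: %d relevance vectors, sigma2 = %.4g, %s after %d iterations\n",
              length(object@relevanceIndices), object@sigma2,
              if (object@converged) "converged" else "not converged",
              object@nIterations))
})

#' LesionSegmentation: output of the KNN lesion segmenter for one subject
#'
#' @slot probabilityMap Volume of lesion probabilities in [0,1].
#' @slot binaryMask Volume, 1 exactly where probability strictly exceeds the
#'   threshold.
#' @slot volumeMl lesion volume in millilitres (mask count x voxel volume /
#'   1000).
#' @slot threshold the probability threshold applied.
#' @export
setClass("LesionSegmentation",
  representation(probabilityMap = "Volume", binaryMask = "Volume",
                 volumeMl = "numeric", threshold = "numeric"))

setValidity("LesionSegmentation", function(object) {
  msg <- character()
  p <- object@probabilityMap@data
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (!all(object@binaryMask@data %in% c(0, 1)))
    msg <- c(msg, "binaryMask must be binary")
  if (!isTRUE(all.equal(object@binaryMask@data,
                        array(as.numeric(p > object@threshold), dim(p)))))
    msg <- c(msg, "binaryMask must equal probability > threshold (strict)")
  expect_ml <- sum(object@binaryMask@data) *
    prod(object@binaryMask@voxelSize) / 1000
  if (!isTRUE(all.equal(object@volumeMl, expect_ml)))
    msg <- c(msg, "volumeMl must equal mask count x voxel volume / 1000")
  if (length(msg)) msg else TRUE
})

#' @rdname LesionSegmentation-class
#' @param x a LesionSegmentation.
#' @export
probabilityMap <- function(x) x@probabilityMap

#' @rdname LesionSegmentation-class
#' @export
lesionMask <- function(x) x@binaryMask

#' @rdname LesionSegmentation-class
#' @export
lesionVolumeMl <- function(x) x@volumeMl

setMethod("show", "LesionSegmentation", function(object) {
  cat(sprintf("LesionSegmentation: %.2f ml at threshold %.2f\n",
              object@volumeMl, object@threshold))
})
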