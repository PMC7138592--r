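#' Aggregate a voxel weight map over atlas regions
#'
#' Per region: the mean voxel weight over the region's voxels inside the
#' analysis mask, and the positive weight mass (sum of max(w, 0)). Regions
#' with no in-mask voxels are excluded with a warning.
#'
#' @param w a \linkS4class{VoxelWeightMap} or a \linkS4class{Volume}.
#' @param atlas an \linkS4class{AtlasLabelMap} on the same grid.
#' @param mask optional binary \linkS4class{Volume} restricting the
#'   aggregation (defaults to all atlas voxels).
#' @return data.frame: label, region, hemisphere, nVoxels, meanWeight,
#'   positiveMass.
#' @export
regionAggregate <- function(w, atlas, mask = NULL) {
  wv <- if (is(w, "VoxelWeightMap")) weightVolume(w) else w
  lab <- atlasLabels(atlas)
  checkSameGrid(wv, lab)
  keep <- volData(lab) > 0
  if (!is.null(mask)) {
    checkSameGrid(mask, lab)
    keep <- keep & volData(mask) == 1
  }
  if (!any(keep)) stop("no atlas voxels inside the weight-map support")
  lv <- as.integer(volData(lab)[keep])
  ww <- volData(wv)[keep]
  labels <- sort(as.integer(names(regionNames(atlas))))
  n <- tabulate(lv, nbins = max(labels))
  missing <- labels[n[labels] == 0L]
  if (length(missing))
    warning(sprintf("region(s) with zero in-mask voxels excluded: %s",
                    paste(regionNames(atlas)[as.character(missing)],
                          collapse = ", ")))
  labels <- labels[n[labels] > 0L]
  sumw <- vapply(labels, function(l) sum(ww[lv == l]), numeric(1))
  posw <- vapply(labels, function(l) sum(pmax(ww[lv == l], 0)), numeric(1))
  data.frame(label = labels,
             region = unname(regionNames(atlas)[as.character(labels)]),
             hemisphere = unname(regionHemisphere(atlas)[as.character(labels)]),
             nVoxels = n[labels],
             meanWeight = sumw / n[labels],
             positiveMass = posw,
             stringsAsFactors = FALSE)
}

#' Regional contribution table across cross-validation folds
#'
#' Within each fold the contribution of region r is
#' \eqn{100 \cdot positiveMass_r / \sum_r positiveMass_r} and regions are
#' ranked by descending contribution (ties broken by lower label). The
#' reported contribution and the expected ranking (ER) are the means across
#' folds. Folds with no positive weight anywhere are degenerate and are
#' skipped; if every fold is degenerate an error is raised.
#'
#' @param perFoldMaps list of \linkS4class{VoxelWeightMap}s (or Volumes),
#'   one per fold.
#' @param atlas an \linkS4class{AtlasLabelMap}.
#' @param mask optional binary analysis mask.
#' @param rankBase 1 (default) for 1-based per-fold ranks, 0 for 0-based.
#' @param testName label attached to the table.
#' @return data.frame sorted by descending contribution: label, region,
#'   hemisphere, contributionPct, meanWeight, er; attributes
#'   \code{testName}, \code{nFolds}, \code{perFoldRanks}.
#' @export
contributionTable <- function(perFoldMaps, atlas, mask = NULL, rankBase = 1,
                              testName = "score") {
  stopifnot(length(perFoldMaps) >= 1L, rankBase %in% c(0, 1))
  aggs <- lapply(perFoldMaps, regionAggregate, atlas = atlas, mask = mask)
  labels <- aggs[[1L]]$label
  nReg <- length(labels)
  contrib <- matrix(NA_real_, nrow = nReg, ncol = length(aggs))
  ranks <- matrix(NA_real_, nrow = nReg, ncol = length(aggs))
  meanw <- matrix(NA_real_, nrow = nReg, ncol = length(aggs))
  degenerate <- logical(length(aggs))
  for (f in seq_along(aggs)) {
    a <- aggs[[f]]
    stopifnot(identical(a$label, labels))
    tot <- sum(a$positiveMass)
    meanw[, f] <- a$meanWeight
    if (tot == 0) { degenerate[f] <- TRUE; next }
    contrib[, f] <- 100 * a$positiveMass / tot
    ord <- order(-contrib[, f], labels)
    ranks[ord, f] <- seq_len(nReg) - (1 - rankBase)
  }
  if (all(degenerate))
    stop("no fold carries positive weight; contributions undefined")
  use <- !degenerate
  out <- data.frame(
    label = labels,
    region = aggs[[1L]]$region,
    hemisphere = aggs[[1L]]$hemisphere,
    contributionPct = rowMeans(contrib[, use, drop = FALSE]),
    meanWeight = rowMeans(meanw),
    er = rowMeans(ranks[, use, drop = FALSE]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$contributionPct, out$label), ]
  rownames(out) <- NULL
  attr(out, "testName") <- testName
  attr(out, "nFolds") <- sum(use)
  attr(out, "perFoldRanks") <- ranks
  out
}

#' Top contributing regions
#'
#' The labels of the first \code{n} rows of a contribution table (fewer if
#' the table is shorter). Ties in contribution were already resolved in
#' favour of the lower label when the table was sorted.
#'
#' @param table a contribution table from \code{\link{contributionTable}}.
#' @param n number of regions (5 by default, matching the reported tables).
#' @return integer vector of region labels.
#' @export
topRegions <- function(table, n = 5L) {
  stopifnot(nrow(table) >= 1L)
  head(table$label, n)
}
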