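# Shared fixtures, all generated in code.

# a small fast phantom spec for unit tests (the acceptance tests use the
# package defaults)
tinySpec <- function(nSubjects = 6L, seed = 1L, ...) {
  phantomSpec(gridShape = c(24L, 28L, 24L), nSubjects = nSubjects,
              seed = seed, ...)
}

# lesion-map-like feature matrix: nonnegative, spatially correlated across
# subjects (shared periventricular pattern scaled by per-subject severity
# plus subject-specific speckle). This is the regime the RVR operates in.
lesionLikeX <- function(n, d, seed = 1L, signalCols = integer(0),
                        signalSd = 1) {
  set.seed(seed)
  sev <- abs(rnorm(n, 1, 0.5))
  pattern <- as.numeric(runif(d) < 0.3) * runif(d, 0.5, 1)
  X <- outer(sev, pattern) + 0.2 * abs(matrix(rnorm(n * d), n))
  for (j in signalCols)
    X[, j] <- X[, j] + abs(rnorm(n, 0, signalSd))
  X
}

# exhaustive KNN probability oracle: all pairwise distances, stable
# (distance, index) sort. Distances accumulated per feature in plain double
# arithmetic.
knnOracle <- function(train, labels, query, k) {
  apply(query, 1, function(q) {
    d2 <- Reduce(`+`, lapply(seq_len(ncol(train)),
                             function(j) (train[, j] - q[j])^2))
    mean(labels[order(d2, seq_along(d2))[seq_len(k)]])
  })
}

# wrap a bare feature matrix as a TrainingPointSet
asTrainingSet <- function(features, labels) {
  new("TrainingPointSet", features = features, labels = as.integer(labels),
      provenance = data.frame(subject_id = "fixture",
                              voxel = seq_len(nrow(features))))
}

# a constant-value Volume on a small grid
constVolume <- function(value, dims = c(6, 6, 6), voxelSize = 2) {
  Volume(array(value, dims), voxelSize = voxelSize)
}
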