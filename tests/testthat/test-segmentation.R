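test_that("feature extraction z-scores intensities and weights coordinates", {
  g <- c(2, 1, 1)
  mask <- Volume(array(1, g), voxelSize = 2)
  s <- SubjectRecord("s1", channels = list(
    t1 = Volume(array(c(10, 20), g), voxelSize = 2),
    flair = Volume(array(c(7, 7), g), voxelSize = 2)))
  cfg <- knnConfig(spatialWeighting = 1)
  ex <- extractFeatures(s, cfg, mask)
  # population-SD convention: mean 15, sd sqrt(((-5)^2 + 5^2)/2) = 5
  expect_equal(unname(ex$features[, "t1"]), c(-1, 1))
  # constant channel maps to all zeros
  expect_equal(unname(ex$features[, "flair"]), c(0, 0))
  # voxel-center mm coordinates: (index0 + 0.5) * pitch
  expect_equal(unname(ex$features[, "x_mm"]), c(1, 3))
  expect_equal(unname(ex$features[, "y_mm"]), c(1, 1))

  # spatial weighting 0 silences the coordinate columns
  ex0 <- extractFeatures(s, knnConfig(spatialWeighting = 0), mask)
  expect_true(all(ex0$features[, c("x_mm", "y_mm", "z_mm")] == 0))

  expect_error(extractFeatures(s, knnConfig(featureChannels = c("t1", "pd")),
                               mask), "missing channel")
})

test_that("training-set sampling honours the fixed+unbalanced policy", {
  g <- c(10, 10, 10)
  mask <- Volume(array(1, g), voxelSize = 2)
  les <- array(0, g); les[1:30] <- 1
  mk <- function(id, seed) {
    set.seed(seed)
    SubjectRecord(id, channels = list(
      t1 = Volume(array(rnorm(1000, 100, 5), g), voxelSize = 2),
      flair = Volume(array(rnorm(1000, 110, 5), g), voxelSize = 2)),
      trueLesionMask = Volume(les, voxelSize = 2))
  }
  s <- mk("a", 1)
  # exactly as many lesion voxels as requested: all selected, none repeated
  cfg <- knnConfig(nLesionPoints = 30L, nNonLesionPoints = 100L)
  tr <- buildTrainingSet(list(s), cfg, mask, seed = 1)
  expect_equal(sum(tr@labels == 1L), 30L)
  expect_equal(sum(tr@labels == 0L), 100L)
  expect_false(any(duplicated(tr@provenance[tr@labels == 1L, ])))

  # shortfall: all available lesion voxels used, with a warning
  cfg2 <- knnConfig(nLesionPoints = 50L, nNonLesionPoints = 100L)
  expect_warning(tr2 <- buildTrainingSet(list(s), cfg2, mask, seed = 1),
                 "using all")
  expect_equal(sum(tr2@labels == 1L), 30L)

  # different seeds: different point sets, identical label counts
  tr3 <- buildTrainingSet(list(s), cfg, mask, seed = 2)
  expect_equal(table(tr3@labels), table(tr@labels))
  expect_false(identical(tr3@provenance$voxel, tr@provenance$voxel))
  # same seed reproduces exactly
  tr4 <- buildTrainingSet(list(s), cfg, mask, seed = 1)
  expect_identical(tr4@features, tr@features)

  # no lesion voxels anywhere -> error
  s0 <- SubjectRecord("b", channels = s@channels,
                      trueLesionMask = Volume(array(0, g), voxelSize = 2))
  expect_error(buildTrainingSet(list(s0), cfg, mask, seed = 1),
               "no lesion voxels")
})

test_that("knn probabilities match the exhaustive oracle and its limits", {
  set.seed(21)
  n <- 60; d <- 5
  tr <- matrix(rnorm(n * d), n)
  lab <- as.integer(runif(n) < 0.4)
  tps <- asTrainingSet(tr, lab)

  # query identical to a lesion training point, k = 1 -> probability 1
  i <- which(lab == 1L)[1]
  expect_equal(knnProbability(tr[i, , drop = FALSE], tps, 1), 1.0)
  # k = all training points -> global lesion fraction for every query
  q <- matrix(rnorm(3 * d), 3)
  expect_equal(knnProbability(q, tps, n), rep(mean(lab), 3))
  # randomized queries vs brute force
  q2 <- matrix(rnorm(30 * d), 30)
  expect_identical(knnProbability(q2, tps, 7), knnOracle(tr, lab, q2, 7))
  # probabilities are exact multiples of 1/k
  p <- knnProbability(q2, tps, 7)
  expect_true(all(p * 7 == round(p * 7)))
  expect_error(knnProbability(q2, tps, n + 1), "exceeds|k must")
})

test_that("knn probability equals the oracle on randomized tied instances", {
  set.seed(77)
  for (r in 1:25) {
    n <- sample(20:200, 1); d <- sample(2:6, 1)
    k <- sample(1:min(n, 12), 1)
    tr <- matrix(round(rnorm(n * d), sample(0:2, 1)), n)  # coarse: many ties
    q <- matrix(round(rnorm(8 * d), 1), 8)
    lab <- as.integer(runif(n) < 0.3)
    tps <- asTrainingSet(tr, lab)
    expect_identical(knnProbability(q, tps, k), knnOracle(tr, lab, q, k))
  }
})

test_that("dice overlap behaves per definition", {
  g <- c(4, 4, 4)
  a <- array(0, g); a[1:4] <- 1
  b <- array(0, g); b[3:6] <- 1
  va <- Volume(a, voxelSize = 2); vb <- Volume(b, voxelSize = 2)
  expect_equal(dice(va, va), 1.0)
  expect_equal(dice(va, Volume(array(0, g) + (a == 0), voxelSize = 2)), 0.0)
  expect_equal(dice(va, vb), 0.5)  # |a|=4, |b|=4, overlap 2
  expect_equal(dice(Volume(array(0, g), 2), Volume(array(0, g), 2)), 1.0)
  expect_error(dice(Volume(a * 2.5, 2), vb), "binary")
})

test_that("segmentation masks are strict-threshold and monotone", {
  spec <- tinySpec(nSubjects = 6L, seed = 8L, includeDti = FALSE)
  coh <- generateCohort(spec)
  bm <- brainMask(coh)
  cfg <- knnConfig(nLesionPoints = 500L, nNonLesionPoints = 2500L)
  tr <- buildTrainingSet(cohortSubjects(coh)[1:4], cfg, bm, seed = 1)
  s <- cohortSubjects(coh)[[5]]

  seg1 <- segmentSubject(s, tr, cfg, bm, threshold = 1.0)
  expect_equal(lesionVolumeMl(seg1), 0)  # strict inequality: empty at 1.0

  vols <- vapply(c(0.2, 0.5, 0.8, 0.9), function(th)
    lesionVolumeMl(segmentSubject(s, tr, cfg, bm, threshold = th)),
    numeric(1))
  expect_true(all(diff(vols) <= 0))  # raising threshold never adds volume

  seg <- segmentSubject(s, tr, cfg, bm)
  expect_equal(volData(lesionMask(seg)),
               array(as.numeric(volData(probabilityMap(seg)) > 0.9),
                     dim(bm)))
  expect_equal(lesionVolumeMl(seg),
               sum(volData(lesionMask(seg))) * voxelVolume(bm) / 1000)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  spec <- tinySpec(nSubjects = 5L, seed = 18L, includeDti = FALSE)
  coh <- generateCohort(spec)
  bm <- brainMask(coh)
  cfg <- knnConfig(nLesionPoints = 400L, nNonLesionPoints = 2000L)
  tr <- buildTrainingSet(cohortSubjects(coh)[1:3], cfg, bm, seed = 2)
  s <- cohortSubjects(coh)[[4]]
  p0 <- probabilityMap(segmentSubject(s, tr, cfg, bm))
  fl <- channel(s, "flair")
  s2 <- SubjectRecord(subjectId(s), channels = list(
    t1 = channel(s, "t1"),
    flair = Volume(volData(fl) * 3.7 + 42, voxelSize(fl))),
    trueLesionMask = trueLesionMask(s))
  p1 <- probabilityMap(segmentSubject(s2, tr, cfg, bm))
  expect_equal(volData(p1), volData(p0), tolerance = 1e-12)
})

test_that("an all-healthy subject segments to (near) zero lesion volume", {
  spec <- tinySpec(nSubjects = 5L, seed = 31L, includeDti = FALSE)
  coh <- generateCohort(spec)
  bm <- brainMask(coh)
  cfg <- knnConfig(nLesionPoints = 500L, nNonLesionPoints = 2500L)
  tr <- buildTrainingSet(cohortSubjects(coh)[1:4], cfg, bm, seed = 3)
  s <- cohortSubjects(coh)[[5]]
  # remove the lesion contrast from both channels, keeping the noise
  im <- spec@intensityModel
  les <- volData(trueLesionMask(s))
  healthy <- SubjectRecord("healthy", channels = list(
    t1 = Volume(volData(channel(s, "t1")) - im$t1$lesionContrast * les,
                voxelSize(bm)),
    flair = Volume(volData(channel(s, "flair")) - im$flair$lesionContrast * les,
                   voxelSize(bm))))
  seg <- segmentSubject(healthy, tr, cfg, bm)
  expect_lte(lesionVolumeMl(seg), 0.1)
})
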