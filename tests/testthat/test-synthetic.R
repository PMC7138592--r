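test_that("cohort generation is deterministic given the seed", {
  c1 <- generateCohort(tinySpec(nSubjects = 3L, seed = 11L))
  c2 <- generateCohort(tinySpec(nSubjects = 3L, seed = 11L))
  for (i in 1:3) {
    s1 <- cohortSubjects(c1)[[i]]; s2 <- cohortSubjects(c2)[[i]]
    expect_identical(volData(trueLesionMask(s1)), volData(trueLesionMask(s2)))
    expect_identical(scores(s1), scores(s2))
    expect_identical(volData(channel(s1, "flair")), volData(channel(s2, "flair")))
  }
  c3 <- generateCohort(tinySpec(nSubjects = 3L, seed = 12L))
  expect_false(identical(volData(trueLesionMask(cohortSubjects(c1)[[1]])),
                         volData(trueLesionMask(cohortSubjects(c3)[[1]]))))
})

test_that("noise-free scores equal intercept plus beta-weighted regional load", {
  sm <- list(TEST = list(intercept = 5, noiseSd = 0,
                         beta = c("Tapetum R" = 1)))
  coh <- generateCohort(tinySpec(nSubjects = 4L, seed = 2L, scoreModel = sm))
  loads <- regionLesionLoads(coh)
  for (i in 1:4) {
    s <- cohortSubjects(coh)[[i]]
    # load is lesion voxel count x voxel volume (mm^3); 2mm voxels -> 8 mm^3
    nvox <- loads[i, "Tapetum R"] / 8
    expect_equal(nvox, round(nvox))
    expect_equal(unname(scores(s)["TEST"]), 5 + loads[i, "Tapetum R"],
                 tolerance = 1e-12)
  }
})

test_that("regressing noise-free scores on true loads recovers beta", {
  sm <- list(TEST = list(intercept = 10, noiseSd = 0,
                         beta = c("Tapetum R" = 0.03,
                                  "Posterior corona radiata R" = -0.01)))
  coh <- generateCohort(tinySpec(nSubjects = 15L, seed = 4L, scoreModel = sm))
  loads <- regionLesionLoads(coh)
  y <- vapply(cohortSubjects(coh), function(s) scores(s)[["TEST"]], numeric(1))
  fit <- lm(y ~ loads[, "Tapetum R"] + loads[, "Posterior corona radiata R"])
  expect_equal(unname(coef(fit)), c(10, 0.03, -0.01), tolerance = 1e-6)
})

test_that("reported lesion volume equals voxel count times voxel volume", {
  coh <- generateCohort(tinySpec(nSubjects = 3L, seed = 6L))
  v <- trueLesionVolumesMl(coh)
  for (i in 1:3) {
    m <- trueLesionMask(cohortSubjects(coh)[[i]])
    expect_equal(unname(v[i]), sum(volData(m)) * voxelVolume(m) / 1000)
  }
})

test_that("raising the lesion base rate does not decrease mean lesion volume", {
  c1 <- generateCohort(tinySpec(nSubjects = 6L, seed = 9L))
  c2 <- generateCohort(tinySpec(nSubjects = 6L, seed = 9L,
                                lesionModel = list(baseRate = 2)))
  expect_gte(mean(trueLesionVolumesMl(c2)), mean(trueLesionVolumesMl(c1)))
})

test_that("lesion probability concentrates near the ventricles", {
  spec <- phantomSpec(nSubjects = 1L, seed = 5L, includeDti = FALSE)
  fld <- lesionProbabilityField(spec)
  p <- volData(fld$field); d <- volData(fld$distanceMm)
  elig <- volData(fld$eligible) == 1
  decay <- 6  # default decay length, mm
  near <- elig & d < decay
  far <- elig & d > 3 * decay
  expect_gt(mean(p[near]), mean(p[far]))
  # empirical lesions follow the field
  coh <- generateCohort(spec)
  les <- volData(trueLesionMask(cohortSubjects(coh)[[1]])) == 1
  expect_gt(mean(d[elig]), mean(d[les]))
})

test_that("degenerate atlas geometry is rejected", {
  as_ <- defaultAtlasSpec()
  as_$wm$x0[1] <- 0.98; as_$wm$x1[1] <- 0.99  # outside the brain ellipsoid
  expect_error(generateCohort(tinySpec(nSubjects = 1L, atlasSpec = as_)),
               "degenerate")
})

test_that("spec validity enforces channel contrast signs and score model", {
  expect_error(tinySpec(intensityModel = list(
    flair = list(wmMean = 110, csfMean = 40, noiseSd = 3,
                 lesionContrast = -10))), "positive")
  expect_error(tinySpec(intensityModel = list(
    t1 = list(wmMean = 100, csfMean = 30, noiseSd = 3,
              lesionContrast = 10))), "negative")
  expect_error(tinySpec(scoreModel = list(
    BAD = list(intercept = 0, noiseSd = 1, beta = c(Nowhere = 1)))),
    "unknown regions")
})

test_that("cohort summary is consistent with its inputs", {
  coh <- generateCohort(tinySpec(nSubjects = 8L, seed = 13L))
  sm <- cohortSummary(coh)
  expect_equal(sm$mean[sm$variable == "lesion_volume_ml"],
               mean(trueLesionVolumesMl(coh)))
  # test-score correlations match a direct partialPearson call
  subs <- cohortSubjects(coh)
  age <- vapply(subs, function(s) covariates(s)$age, numeric(1))
  edu <- vapply(subs, function(s) covariates(s)$education, numeric(1))
  sexF <- as.numeric(vapply(subs, function(s) covariates(s)$sex,
                            character(1)) == "F")
  y <- vapply(subs, function(s) scores(s)[["MMSE"]], numeric(1))
  pc <- partialPearson(y, age, cbind(sexF, edu))
  expect_equal(sm$r_age[sm$variable == "MMSE"], pc$r)
  expect_equal(sm$p_age[sm$variable == "MMSE"], pc$p)

  # single-subject cohort: SDs and correlations are NA, means still defined
  coh1 <- generateCohort(tinySpec(nSubjects = 1L, seed = 14L))
  sm1 <- cohortSummary(coh1)
  expect_true(all(is.na(sm1$sd)))
  expect_true(all(is.na(sm1$r_wml)))
  expect_false(any(is.na(sm1$mean)))
})
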