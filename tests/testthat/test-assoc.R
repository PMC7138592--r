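test_that("partial correlation reduces to plain Pearson without covariates", {
  set.seed(14)
  for (r in 1:5) {
    x <- rnorm(25); y <- rnorm(25)
    pc <- partialPearson(x, y)
    ct <- cor.test(x, y)
    expect_equal(pc$r, unname(ct$estimate))
    expect_equal(pc$p, ct$p.value)
  }
})

test_that("partial correlation agrees with the inverse-correlation-matrix formula", {
  set.seed(15)
  for (r in 1:10) {
    n <- 40; q <- sample(1:3, 1)
    Z <- matrix(rnorm(n * q), n)
    x <- rnorm(n) + Z %*% rnorm(q)
    y <- rnorm(n) + Z %*% rnorm(q)
    pc <- partialPearson(x, y, Z)
    # independent oracle: negated scaled off-diagonal of the inverse of the
    # correlation matrix of (x, y, covariates)
    Om <- solve(cor(cbind(x, y, Z)))
    rOracle <- -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
    expect_equal(pc$r, rOracle, tolerance = 1e-10)
  }
})

test_that("partial correlation handles degenerate inputs per contract", {
  set.seed(16)
  Z <- matrix(rnorm(30), 15)
  # y a perfect linear function of the covariates -> residual correlation 0
  y <- drop(Z %*% c(2, -1)) + 3
  x <- rnorm(15)
  expect_error(partialPearson(x, y, Z), "constant")
  # rank-deficient covariates
  Zbad <- cbind(Z[, 1], 2 * Z[, 1])
  expect_error(partialPearson(rnorm(15), rnorm(15), Zbad), "rank-deficient")
  expect_error(partialPearson(rnorm(4), rnorm(4), Z[1:4, ]), "need n")
})

test_that("region means match a brute-force voxel loop", {
  at <- local({
    g <- c(5, 5, 5)
    lab <- array(0L, g); lab[1:30] <- 1L; lab[31:80] <- 2L
    AtlasLabelMap(Volume(lab, voxelSize = 2), c("1" = "A", "2" = "B"))
  })
  expect_equal(unname(extractRegionMeans(constVolume(0.4, c(5, 5, 5)), at,
                                         c(1, 2))), c(0.4, 0.4))
  set.seed(17)
  mv <- Volume(array(rnorm(125, 0.5, 0.1), c(5, 5, 5)), voxelSize = 2)
  rm_ <- extractRegionMeans(mv, at, c(1, 2))
  lab <- volData(atlasLabels(at)); md <- volData(mv)
  for (l in 1:2) {
    acc <- 0; n <- 0
    for (v in seq_along(lab)) if (lab[v] == l) { acc <- acc + md[v]; n <- n + 1 }
    expect_equal(unname(rm_[l]), acc / n)
  }
  expect_error(extractRegionMeans(mv, at, 3), "no voxels")
})

test_that("diffusion metrics degrade inside lesion-bearing regions", {
  coh <- generateCohort(tinySpec(nSubjects = 6L, seed = 26L))
  loads <- regionLesionLoads(coh)
  labels <- seq_len(ncol(loads))
  fa <- regionMetricProfiles(coh, "fa", labels)
  ad <- regionMetricProfiles(coh, "ad", labels)
  hi <- colMeans(loads) > quantile(colMeans(loads), 0.7)
  lo <- colMeans(loads) < quantile(colMeans(loads), 0.3)
  expect_lt(mean(fa[, hi]), mean(fa[, lo]))   # FA decreases in lesions
  expect_gt(mean(ad[, hi]), mean(ad[, lo]))   # AD increases in lesions
})

test_that("multiple regression matches a manual OLS computation", {
  # n = 8, k = 2 textbook computation
  X <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8),
             c(2, 1, 4, 3, 6, 5, 8, 7))
  y <- c(3, 4, 8, 9, 13, 14, 19, 21)
  res <- multivariateRegression(y, X)
  Xd <- cbind(1, X)
  betaHat <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  resid <- y - Xd %*% betaHat
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  Fm <- ((sst - sse) / 2) / (sse / (8 - 3))
  expect_equal(unname(res$coefficients), drop(betaHat), tolerance = 1e-12)
  expect_equal(res$F, Fm, tolerance = 1e-12)
  expect_equal(res$p, pf(Fm, 2, 5, lower.tail = FALSE))
  expect_equal(res$dfModel, 2L)
  expect_equal(res$dfResid, 5L)
})

test_that("regression F is invariant to rescaling a predictor column", {
  set.seed(18)
  X <- matrix(rnorm(60), 20)
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(20)
  f1 <- multivariateRegression(y, X)$F
  X2 <- X; X2[, 2] <- X2[, 2] * 1000 + 7
  expect_equal(multivariateRegression(y, X2)$F, f1, tolerance = 1e-10)
})

test_that("perfect fits and collinear designs follow the contract", {
  X <- matrix(rnorm(30), 10)
  y <- drop(X %*% c(1, 2, 3)) + 5  # exact linear function, no noise
  res <- multivariateRegression(y, X)
  expect_true(is.infinite(res$F))
  expect_equal(res$p, 0)
  Xc <- cbind(X, X[, 1] * 2)
  expect_error(multivariateRegression(y, Xc), "collinear")
})

test_that("regression can adjust for covariates via the partial F", {
  set.seed(19)
  n <- 40
  cov_ <- matrix(rnorm(n), n)
  X <- matrix(rnorm(n * 2), n) + drop(cov_) * 0.5
  y <- drop(cov_ %*% 2) + rnorm(n)  # y depends only on the covariate
  resAdj <- multivariateRegression(y, X, covariates = cov_)
  resRaw <- multivariateRegression(y, X)
  expect_gt(resRaw$F, resAdj$F)  # adjustment removes the spurious signal
  expect_gt(resAdj$p, 0.05)
})
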