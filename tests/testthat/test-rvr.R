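test_that("frozen hyperparameters reproduce the ridge closed form", {
  set.seed(101)
  for (r in 1:3) {
    N <- 50; D <- 200
    X <- matrix(rnorm(N * D), N)
    y <- rnorm(N)
    a <- exp(runif(1, -2, 2)); s2 <- exp(runif(1, -2, 0))
    st <- fitRVR(X, y, rvrControl(fixedAlpha = a, fixedSigma2 = s2))
    Phi <- cbind(tcrossprod(X), 1)
    muRidge <- drop(solve(crossprod(Phi) + a * s2 * diag(ncol(Phi)),
                          crossprod(Phi, y)))
    expect_lt(max(abs(posteriorMean(st) - muRidge)) / max(abs(muRidge)),
              1e-8)
  }
})

test_that("a noise-free realizable target is reproduced by few relevance vectors", {
  set.seed(7)
  X <- matrix(rnorm(30 * 40), 30)
  y <- tcrossprod(X)[, 11]  # y is exactly one kernel column
  st <- fitRVR(X, y)
  pred <- predictRVR(st, X)
  expect_lt(max(abs(pred - y)) / max(abs(y)), 1e-6)
  expect_lte(length(relevanceVectors(st)), 3L)
})

test_that("the log marginal likelihood is non-decreasing over iterations", {
  set.seed(31)
  for (r in 1:10) {
    X <- lesionLikeX(25, 150, seed = 1000 + r)
    y <- rnorm(25)
    st <- fitRVR(X, y)
    expect_gte(min(diff(st@logMarginal)), -1e-6)
  }
})

test_that("pure-noise targets prune to few relevance vectors for low-rank features", {
  # structured (low-rank) features: the pruning dynamics concentrate the
  # model on a handful of kernel columns
  set.seed(55)
  kept <- vapply(1:5, function(r) {
    X <- matrix(rnorm(60 * 5), 60)
    y <- rnorm(60)
    length(relevanceVectors(fitRVR(X, y)))
  }, numeric(1))
  expect_true(all(kept <= 6))  # <= 10% of the 60 kernel bases
})

test_that("our sparse fits agree with an independent RVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(19)
  X <- matrix(rnorm(50 * 4), 50)
  w <- c(1.5, -2, 0, 0)
  y <- drop(X %*% w) + rnorm(50, 0, 0.3)
  st <- fitRVR(X, y)
  kl <- kernlab::rvm(X, y, kernel = "vanilladot", kpar = list())
  Xte <- matrix(rnorm(40 * 4), 40)
  p1 <- predictRVR(st, Xte)
  p2 <- drop(kernlab::predict(kl, Xte))
  expect_gt(cor(p1, p2), 0.99)
  expect_lt(length(relevanceVectors(st)), 25L)
})

test_that("prediction is linear in the input and consistent on training data", {
  set.seed(12)
  X <- lesionLikeX(20, 80, seed = 3)
  y <- drop(X %*% rnorm(80, 0, 0.3)) + rnorm(20, 0, 0.2)
  st <- fitRVR(X, y)
  x1 <- matrix(rnorm(80), 1)
  f0 <- predictRVR(st, matrix(0, 1, 80))
  # x = 0 -> bias alone
  nrv <- length(relevanceVectors(st))
  expect_equal(drop(f0), posteriorMean(st)[nrv + 1L])
  # linear-kernel identity f(2x) - f(0) = 2 (f(x) - f(0))
  expect_equal(drop(predictRVR(st, 2 * x1) - f0),
               2 * drop(predictRVR(st, x1) - f0), tolerance = 1e-10)
  expect_error(predictRVR(st, matrix(0, 1, 79)), "dimension")
})

test_that("back-projection reproduces kernel predictions exactly", {
  set.seed(40)
  g <- c(6, 6, 6)
  maskArr <- array(0, g); maskArr[sample(216, 90)] <- 1
  mask <- Volume(maskArr, voxelSize = 2)
  D <- 90
  X <- lesionLikeX(22, D, seed = 8)
  y <- drop(X %*% rnorm(D, 0, 0.3)) + rnorm(22, 0, 0.3)
  st <- fitRVR(X, y)
  wmap <- backprojectWeights(st, mask, testName = "t", foldId = 1)
  wv <- volData(weightVolume(wmap))
  expect_true(all(wv[maskArr == 0] == 0))  # zero outside the analysis mask
  wvec <- wv[maskArr == 1]
  nrv <- length(relevanceVectors(st))
  bias <- posteriorMean(st)[nrv + 1L]
  for (i in 1:20) {
    x <- rnorm(D)
    expect_equal(drop(x %*% wvec) + bias,
                 drop(predictRVR(st, matrix(x, 1))), tolerance = 1e-8)
  }
})

test_that("an empty relevance set yields a bias-only predictor and zero map", {
  st <- new("RVRState", relevanceIndices = integer(0), mu = 3.5,
            alpha = 1e-6, sigma2 = 1, kernel = "linear",
            rvFeatures = matrix(numeric(0), 0, 0), converged = TRUE,
            nIterations = 1L, logMarginal = 0)
  expect_equal(predictRVR(st, matrix(rnorm(10), 2)), c(3.5, 3.5))
  mask <- constVolume(1, c(3, 3, 3))
  wmap <- backprojectWeights(st, mask)
  expect_true(all(volData(weightVolume(wmap)) == 0))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 5)
  expect_error(fitRVR(X, rep(2, 5)), "constant")
  expect_error(fitRVR(X, c(1, 2, NA, 4, 5)), "finite")
  expect_error(fitRVR(X[1:2, ], 1:2), "at least 3")
})
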