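test_that("kernel values match their closed forms and bounds", {
  expect_equal(kernelValue("gf", 0, 1), 1)
  expect_equal(kernelValue("rsf", 0, 2), 0.5)
  expect_equal(kernelValue("imqf", 0, 2), 0.5)
  expect_equal(kernelValue("gf", sqrt(2) * 3, 3), exp(-1))
  expect_error(kernelValue("gf", 1, 0), "sigma")
  expect_error(kernelValue("gf", -1, 1), "nonnegative")

  # strictly decreasing in r for all kernels
  r <- seq(0, 5, by = 0.1)
  for (k in c("gf", "rsf", "imqf"))
    expect_true(all(diff(kernelValue(k, r, 1.3)) < 0), label = k)
})

test_that("k-means centers are deterministic and recover separated blobs", {
  set.seed(1)
  blobA <- matrix(rnorm(100, 0, 0.5), 50, 2)
  blobB <- matrix(rnorm(100, 20, 0.5), 50, 2)
  X <- rbind(blobA, blobB)
  c1 <- fitCenters(X, 2, seed = 7)
  c2 <- fitCenters(X, 2, seed = 7)
  expect_identical(c1, c2)
  # one center inside each blob: assignment purity 100%
  d <- as.matrix(dist(rbind(X, c1)))[1:100, 101:102]
  assign <- apply(d, 1, which.min)
  expect_length(unique(assign[1:50]), 1L)
  expect_length(unique(assign[51:100]), 1L)
  expect_false(assign[1] == assign[51])
})

test_that("centers degrade gracefully at the data's cardinality", {
  pts <- matrix(c(0, 0, 1, 1, 4, 0), 3, 2, byrow = TRUE)
  ctr <- fitCenters(pts, 3, seed = 1)
  expect_equal(ctr[order(ctr[, 1]), ], pts[order(pts[, 1]), ],
               tolerance = 1e-9)
  expect_error(fitCenters(pts, 4, seed = 1), "lower p")
})

test_that("the nearest-neighbour width rule is exact and homogeneous", {
  expect_equal(estimateWidth(matrix(c(0, 1)), kNN = 1), 1)
  expect_equal(estimateWidth(matrix(c(0, 1, 3)), kNN = 1), 4 / 3)
  ctr <- matrix(rnorm(20), 10, 2)
  expect_equal(estimateWidth(5 * ctr), 5 * estimateWidth(ctr),
               tolerance = 1e-12)
  expect_warning(s <- estimateWidth(matrix(1, 3, 2)), "coincide")
  expect_equal(s, 1e-6)
})

test_that("MSE weights agree with the normal-equations oracle", {
  set.seed(42)
  X <- matrix(rnorm(1600), 200, 8)
  bTrue <- c(1.5, rnorm(8))
  y <- cbind(1, X) %*% bTrue + rnorm(200, sd = 0.1)
  fit <- fitWeights(cbind(1, X), drop(y))
  b <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(fit$weights, drop(b), tolerance = 1e-8)
  expect_equal(fit$residualVariance, oracleRSS(X, drop(y)) / 200,
               tolerance = 1e-8)
  # noise variance recovered to within 30%
  expect_lt(abs(fit$residualVariance - 0.01) / 0.01, 0.3)
})

test_that("targets in the design span give zero residual variance", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(300), 100, 3))
  y <- drop(X %*% c(2, -1, 0.5, 3))
  expect_lt(fitWeights(X, y)$residualVariance / var(y), 1e-10)

  # intercept-only design: residual variance = mean squared deviation
  y2 <- rnorm(50)
  expect_equal(fitWeights(matrix(1, 50, 1), y2)$residualVariance,
               mean((y2 - mean(y2))^2), tolerance = 1e-12)
})

test_that("adding basis columns never increases residual variance", {
  set.seed(8)
  X <- matrix(rnorm(1000), 200, 5)
  y <- rnorm(200)
  rv <- vapply(1:5, function(k)
    fitWeights(cbind(1, X[, 1:k, drop = FALSE]), y)$residualVariance, 1)
  expect_true(all(diff(rv) <= 1e-10))
})

test_that("the full RBF pipeline fits a smooth nonlinear function", {
  set.seed(5)
  x <- matrix(runif(400, -3, 3))
  y <- drop(sin(x)) + rnorm(400, sd = 0.05)
  fit <- rbfFit(x, y, p = 12, seed = 2)
  expect_lt(fit$residualVariance, 0.01)
  expect_equal(length(fit$weights), 13L)  # intercept + 12 centers
  expect_gt(fit$sigma, 0)
})
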