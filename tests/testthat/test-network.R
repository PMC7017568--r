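test_that("random networks have zero diagonal and the requested density", {
  B <- generateRandomNetwork(6, 0.2, seed = 1)
  expect_equal(dim(B), c(6, 6))
  expect_true(all(diag(B) == 0))
  expect_true(all(B %in% 0:1))

  expect_equal(generateRandomNetwork(2, 0, seed = 1), matrix(0L, 2, 2))
  expect_equal(sum(generateRandomNetwork(4, 1, seed = 1)), 12L)

  # empirical density over many draws within 3 standard errors of the ratio
  nOff <- 30
  draws <- 400
  ones <- sum(vapply(seq_len(draws),
                     function(s) sum(generateRandomNetwork(6, 0.2, seed = s)),
                     1L))
  phat <- ones / (draws * nOff)
  se <- sqrt(0.2 * 0.8 / (draws * nOff))
  expect_lt(abs(phat - 0.2), 3 * se)
})

test_that("network generation is reproducible and validates input", {
  expect_identical(generateRandomNetwork(5, 0.3, seed = 42),
                   generateRandomNetwork(5, 0.3, seed = 42))
  expect_error(generateRandomNetwork(1, 0.2), "n")
  expect_error(generateRandomNetwork(4, 1.5), "connectionRatio")
  # exact-count variant pins the realised edge count
  expect_equal(sum(generateRandomNetwork(5, 0.2, seed = 3,
                                         exactCount = TRUE)), 4L)
})

test_that("weight matrices are supported exactly on the adjacency", {
  B <- generateRandomNetwork(5, 0.4, seed = 9)
  W <- makeWeightMatrix(B, 1.7)
  expect_true(all((W > 0) == (B == 1)))
  expect_true(all(diag(W) == 0))
  expect_error(makeWeightMatrix(B, -1), "positive")
  expect_error(makeWeightMatrix(matrix(2, 2, 2)), "diagonal|binary")
})

test_that("neuron parameter validation enforces the membrane identities", {
  p <- neuronParams()
  expect_equal(p$tauM, p$rM * p$cM)
  expect_error(neuronParams(tauM = 20, rM = 10, cM = 5), "rM")
  expect_error(neuronParams(vReset = -60, eM = -70), "vReset")
  expect_error(neuronParams(tauS = 0), "tauS")
})

test_that("seed mixing is deterministic, keyed, and in integer range", {
  expect_identical(mixSeed(7, c(1, 6, 3)), mixSeed(7, c(1, 6, 3)))
  expect_false(mixSeed(7, c(1, 6, 3)) == mixSeed(7, c(1, 6, 4)))
  s <- vapply(1:200, function(i) mixSeed(123, c(2, i)), 1L)
  expect_true(all(s >= 1 & s < 2^31 - 1))
  expect_equal(length(unique(s)), 200L)
})
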