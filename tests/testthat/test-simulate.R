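test_that("synaptic current matches the closed-form exponential sum", {
  W <- matrix(1, 1, 1)
  empty <- SpikeRaster(list(numeric(0)), duration = 100)
  expect_equal(synapticCurrent(50, 1, W, empty, tauS = 5), 0)

  one <- SpikeRaster(list(10), duration = 100)
  expect_equal(synapticCurrent(10, 1, matrix(3, 1, 1), one, tauS = 5), 3)

  # spikes at t - tauS and t - 2 tauS with unit weight: e^-1 + e^-2
  two <- SpikeRaster(list(c(10, 15)), duration = 100)
  expect_equal(synapticCurrent(20, 1, W, two, tauS = 5),
               exp(-1) + exp(-2), tolerance = 1e-12)

  # future spikes contribute nothing
  expect_equal(synapticCurrent(5, 1, W, one, tauS = 5), 0)
})

test_that("a quiescent neuron stays at rest and decays monotonically", {
  p <- neuronParams(noiseMean = 0, noiseSd = 0)
  r <- simulateNetwork(matrix(0, 1, 1), p, duration = 200, dt = 1,
                       returnVoltage = TRUE)
  expect_length(spikeTimes(r)[[1]], 0)
  expect_true(all(abs(attr(r, "voltage")[, 1] - p$eM) < 1e-12))

  # started above rest, |V - E_m| is non-increasing
  r2 <- simulateNetwork(matrix(0, 1, 1), p, duration = 200, dt = 1,
                        v0 = -60, returnVoltage = TRUE)
  dev <- abs(attr(r2, "voltage")[, 1] - p$eM)
  expect_true(all(diff(dev) <= 1e-12))
  expect_lt(dev[200], 0.01)
})

test_that("constant suprathreshold drive reproduces the closed-form ISI", {
  p <- neuronParams(noiseMean = 2, noiseSd = 0)
  dt <- 0.05
  r <- simulateNetwork(matrix(0, 1, 1), p, duration = 2000, dt = dt)
  st <- spikeTimes(r)[[1]]
  expect_gt(length(st), 10)
  isi <- diff(st)
  drive <- p$eM + p$rM * p$noiseMean
  isiTheory <- p$tRef +
    p$tauM * log((drive - p$vReset) / (drive - p$vTh))
  expect_lt(max(abs(isi - isiTheory)), 2 * dt + 1e-9)
})

test_that("an excitatory edge raises the postsynaptic rate", {
  B <- matrix(0, 2, 2); B[2, 1] <- 1
  rOn <- simulateNetwork(makeWeightMatrix(B, 2), duration = 6e4, seed = 3)
  rOff <- simulateNetwork(matrix(0, 2, 2), duration = 6e4, seed = 3)
  expect_gt(length(spikeTimes(rOn)[[2]]), length(spikeTimes(rOff)[[2]]))
  # the driver neuron itself is unaffected (same noise stream)
  expect_identical(spikeTimes(rOn)[[1]], spikeTimes(rOff)[[1]])
})

test_that("simulation is reproducible and guards unstable steps", {
  W <- makeWeightMatrix(generateRandomNetwork(3, 0.4, seed = 2))
  r1 <- simulateNetwork(W, duration = 5000, seed = 11)
  r2 <- simulateNetwork(W, duration = 5000, seed = 11)
  expect_identical(spikeTimes(r1), spikeTimes(r2))
  expect_error(simulateNetwork(W, duration = 1000, dt = 4), "unstable")
  expect_error(simulateNetwork(matrix(0, 2, 3)), "square")
})

test_that("halving the Euler step changes network spike counts by < 5%", {
  fx <- makeFixture("fig1-like-6node", duration = 2000, seed = 5)
  c1 <- sum(lengths(spikeTimes(
    simulateNetwork(fx$W, duration = 6e4, dt = 1, seed = 9))))
  c2 <- sum(lengths(spikeTimes(
    simulateNetwork(fx$W, duration = 6e4, dt = 0.5, seed = 9))))
  expect_lt(abs(c1 - c2) / c1, 0.05)
})

test_that("binning counts, indicates, and conserves spikes", {
  r <- SpikeRaster(list(c(3, 12, 19)), duration = 30)
  expect_equal(seriesData(binSpikes(r, 10, "count"))[, 1], c(1, 2, 0))
  expect_equal(seriesData(binSpikes(r, 10, "indicator"))[, 1], c(1, 1, 0))

  # 5 s at 10 ms -> 500 bins
  r5 <- simulateNetwork(matrix(0, 2, 2), duration = 5000, seed = 4)
  expect_equal(nBins(binSpikes(r5, 10)), 500L)

  # count-mode conservation on a simulated raster
  s <- binSpikes(r5, 10, "count")
  expect_equal(unname(colSums(seriesData(s))),
               lengths(spikeTimes(r5)))

  # empty raster -> all-zero series, not an error
  empty <- SpikeRaster(list(numeric(0), numeric(0)), duration = 100)
  expect_true(all(seriesData(binSpikes(empty, 10)) == 0))
  expect_error(binSpikes(r, 0), "binWidth")
})
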