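test_that("lag embedding aligns targets with their past values", {
  e <- lagEmbed(1:5, m = 2, tau = 0)
  expect_equal(e$targets, 3:5)
  expect_equal(e$lags, matrix(c(2, 3, 4, 1, 2, 3), 3, 2))
  expect_equal(e$nEff, 3)

  e2 <- lagEmbed(1:5, m = 2, tau = 1)
  expect_equal(e2$targets, 4:5)

  e3 <- lagEmbed(rep(1, 10), m = 3)
  expect_true(all(e3$lags == 1))
  expect_error(lagEmbed(1:4, m = 4), "too short")
})

test_that("linear Granger causality equals the normal-equations oracle", {
  for (s in 1:5) {
    d <- simCoupled(800, coef = 0.5, seed = s)
    got <- linearGCPair(d$x, d$y)$yToX
    want <- oracleLinearF(d$x, d$y)
    expect_equal(causalityIndex(got), want$F, tolerance = 1e-8)
    expect_equal(got@sigmaFull, want$sigmaFull, tolerance = 1e-8)
    expect_equal(got@sigmaReduced, want$sigmaReduced, tolerance = 1e-8)
    expect_equal(got@nSamples, want$nEff)
  }
})

test_that("a lag-1 linear coupling is detected in the right direction", {
  hits <- 0; falseDir <- 0
  for (s in 1:20) {
    d <- simCoupled(1500, coef = 0.8, seed = 100 + s)
    r <- linearGCPair(d$x, d$y)
    hits <- hits + decision(r$yToX)
    falseDir <- falseDir + decision(r$xToY)
  }
  expect_gte(hits, 19)       # power ~ 1
  expect_lte(falseDir, 2)    # anti-causal direction at the nominal rate
})

test_that("independent channels are rejected at close to the nominal rate", {
  rej <- 0
  for (s in 1:200) {
    d <- simNull(500, seed = 300 + s)
    rej <- rej + decision(linearGCPair(d$x, d$y)$yToX)
  }
  # alpha = 0.01: expect ~2 rejections in 200; allow 3 SE of binomial noise
  expect_lte(rej, 2 + 3 * sqrt(200 * 0.01 * 0.99) + 1)
})

test_that("RBF test detects a quadratic coupling the linear test misses", {
  nHit <- 0; lHit <- 0
  for (s in 1:25) {
    set.seed(700 + s)
    N <- 600
    y <- rnorm(N)
    x <- 0.8 * c(0, y[-N])^2 + rnorm(N, sd = 0.5)
    nHit <- nHit + decision(nonlinearGCPair(x, y, p = 10, seed = s)$yToX)
    lHit <- lHit + decision(linearGCPair(x, y)$yToX)
  }
  expect_gte(nHit, 22)
  expect_lt(lHit, nHit - 10)
})

test_that("a smooth monotone coupling is caught by the nonlinear test", {
  hits <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    N <- 600
    y <- rnorm(N)
    x <- tanh(2 * c(0, y[-N])) + rnorm(N, sd = 0.3)
    hits <- hits + decision(nonlinearGCPair(x, y, p = 10, seed = s)$yToX)
  }
  expect_gte(hits, 9)
})

test_that("a shifted copy yields a large one-directional index", {
  set.seed(12)
  x <- rnorm(800)
  y <- c(0, x[-800])   # y is x delayed by one step: x drives y
  r <- nonlinearGCPair(x, y, p = 10, seed = 1)
  expect_gt(causalityIndex(r$xToY), 1)
  expect_true(decision(r$xToY))
  expect_false(decision(r$yToX))
})

test_that("decisions are invariant to channel offset and positive scale", {
  d <- simCoupled(600, seed = 77)
  r1 <- nonlinearGCPair(d$x, d$y, p = 8, seed = 3)$yToX
  r2 <- nonlinearGCPair(5 + 2 * d$x, -1 + 0.3 * d$y, p = 8, seed = 3)$yToX
  expect_equal(causalityIndex(r1), causalityIndex(r2), tolerance = 1e-8)
  expect_identical(decision(r1), decision(r2))
})

test_that("nesting keeps F nonnegative and ln/ratio decisions agree", {
  for (s in 1:60) {
    set.seed(1200 + s)
    N <- 150
    x <- rnorm(N); y <- rnorm(N)
    r <- if (s %% 2) linearGCPair(x, y, m = 3)
         else nonlinearGCPair(x, y, m = 3, p = 5, seed = s)
    for (g in r) {
      expect_gte(causalityIndex(g), 0)
      # ln(S2/S1) > 0 exactly when S2/S1 > 1: the two report scales order
      # every instance identically, so decisions cannot differ
      expect_identical(causalityIndex(g) > 0, g@sigmaReduced > g@sigmaFull)
    }
  }
})

test_that("the F-test handles its boundary cases", {
  expect_equal(significanceTest(10, 10, 100, 5, 11), 1)
  expect_warning(p <- significanceTest(0, 1, 100, 5, 11), "perfect")
  expect_equal(p, 0)
  expect_error(significanceTest(-1, 1, 100, 5, 11), "nonnegative")
  expect_error(significanceTest(1, 1, 10, 5, 11), "nSamples")
  # reduction below the full model is clamped, never negative evidence
  expect_equal(significanceTest(10, 9, 100, 5, 11), 1)
})

test_that("permutation and parametric p-values agree on a clean instance", {
  d <- simCoupled(800, coef = 0.25, seed = 5)
  m <- cbind(x = d$x, y = d$y)
  pPar <- pValue(conditionalGC(m, 2, 1, method = "lgcim", seed = 1))
  pPerm <- pValue(conditionalGC(m, 2, 1, method = "lgcim", seed = 1,
                                test = "permutation", nPerm = 199))
  expect_lt(abs(pPar - pPerm), 0.05)

  # null instance: both tests should accept
  d0 <- simNull(800, seed = 6)
  m0 <- cbind(x = d0$x, y = d0$y)
  expect_gt(pValue(conditionalGC(m0, 2, 1, method = "lgcim", seed = 1,
                                 test = "permutation", nPerm = 199)), 0.05)
})

test_that("conditioning separates direct from indirect influence", {
  supp <- 0; pairHit <- 0; directHit <- 0
  for (k in 1:15) {
    fx <- makeFixture("chain3", duration = 6e4, seed = 4000 + k)
    pw <- conditionalGC(fx$series, 3, 1, conditioning = "none", seed = k)
    cd <- conditionalGC(fx$series, 3, 1, conditioning = "all", seed = k)
    dr <- conditionalGC(fx$series, 2, 1, conditioning = "all", seed = k)
    pairHit <- pairHit + decision(pw)
    supp <- supp + (decision(pw) && !decision(cd))
    directHit <- directHit + decision(dr)
  }
  expect_gte(pairHit, 8)     # the indirect path is visible pairwise
  expect_gte(supp, 6)        # and mostly suppressed under conditioning
  expect_gte(directHit, 14)  # the true direct edge is always found
})

test_that("degenerate channels raise a clear error", {
  expect_error(linearGCPair(rep(1, 100), rnorm(100)), "degenerate")
  m <- cbind(rnorm(100), rep(0, 100), rnorm(100))
  expect_error(conditionalGC(m, 2, 1), "degenerate")
})

test_that("GCResult exposes its components through accessors", {
  d <- simCoupled(400, seed = 9)
  r <- linearGCPair(d$x, d$y)$yToX
  expect_s4_class(r, "GCResult")
  expect_true(is.finite(r@crossCov))
  expect_identical(decision(r), pValue(r) < r@alpha)
  expect_output(show(r), "GCResult")
})
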