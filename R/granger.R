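# Linear and nonlinear conditional Granger causality.
#
# The full model for the directed pair y -> x regresses the target x on an
# intercept, the RBF expansion (or raw lag block, linear method) of x's own
# past, of y's past, and of the past of every conditioning channel. The
# reduced model drops y's block while keeping every other basis column
# identical, so the reduced residual variance can never fall below the full
# one (up to the ridge term) and F = ln(sigma_reduced / sigma_full) >= 0.

#' Lag embedding of a single channel
#'
#' Builds the regression view of a series: targets `x^k = x[k + m + tau]`
#' and lag vectors `X^k = (x[k + m - 1], ..., x[k])` (most recent value
#' first) for `k = 1, ..., N - m - tau`, where `m` is the model order and
#' `tau` a pure delay.
#'
#' @param x numeric series.
#' @param m model order (number of lags).
#' @param tau pure delay (default 0).
#' @return list with `targets` (length `nEff`), `lags`
#'   (`nEff x m` matrix), `m`, `tau`, `nEff = length(x) - m - tau`.
#' @export
#' @examples
#' lagEmbed(1:5, m = 2)   # targets 3,4,5; lag rows (2,1), (3,2), (4,3)
lagEmbed <- function(x, m, tau = 0) {
  N <- length(x)
  nEff <- N - m - tau
  if (nEff < 1) stop("series too short for this (m, tau)")
  targets <- x[seq_len(nEff) + m + tau]
  lags <- sapply(seq_len(m), function(l) x[seq_len(nEff) + m - l])
  lags <- matrix(lags, nrow = nEff, ncol = m)
  list(targets = targets, lags = lags, m = m, tau = tau, nEff = nEff)
}

# z-score columns; constant columns are flagged as degenerate.
.zscoreChannels <- function(mat) {
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, sd)
  degenerate <- !is.finite(sdv) | sdv == 0
  z <- sweep(mat, 2L, mu)
  z[, !degenerate] <- sweep(z[, !degenerate, drop = FALSE], 2L,
                            sdv[!degenerate], "/")
  list(z = z, degenerate = degenerate)
}

# Build one predictor block per channel (shared k-range) plus the aligned
# target vectors. method "lgcim": raw lag block; "ngcim": RBF basis with
# per-channel k-means centers and kNN width. p is capped per channel at the
# number of distinct lag vectors.
.gcBlocks <- function(mat, m, tau, method = "ngcim", kernel = "gf",
                      p = 20L, seed = NULL, kNN = 2L) {
  n <- ncol(mat)
  zs <- .zscoreChannels(mat)
  blocks <- vector("list", n)
  targets <- matrix(NA_real_, nrow(mat) - m - tau, n)
  degenerate <- zs$degenerate
  for (c in seq_len(n)) {
    if (degenerate[c]) next
    emb <- lagEmbed(zs$z[, c], m, tau)
    targets[, c] <- emb$targets
    if (method == "lgcim") {
      blocks[[c]] <- emb$lags
    } else {
      u <- unique(emb$lags)
      pc <- min(p, nrow(u))
      if (pc < 2L) { degenerate[c] <- TRUE; next }
      centers <- fitCenters(emb$lags, pc,
                            seed = if (is.null(seed)) NULL
                                   else mixSeed(seed, c))
      sigma <- estimateWidth(centers, kNN)
      blocks[[c]] <- rbfBasis(emb$lags, centers, sigma, kernel)
    }
  }
  list(blocks = blocks, targets = targets, degenerate = degenerate,
       nEff = nrow(mat) - m - tau)
}

# Assemble the joint design across a set of channels and precompute the
# Gram matrix once; individual full/reduced fits are then cheap Cholesky
# solves on column subsets.
.gcEngine <- function(blocks, channels, lambda = 1e-8) {
  used <- channels[!vapply(blocks[channels], is.null, TRUE)]
  G <- cbind(1, do.call(cbind, blocks[used]))
  cols <- vector("list", length(blocks))
  at <- 2L
  for (c in used) {
    w <- ncol(blocks[[c]])
    cols[[c]] <- seq.int(at, at + w - 1L)
    at <- at + w
  }
  A <- crossprod(G)
  list(G = G, A = A, cols = cols, used = used,
       pen = lambda * mean(diag(A)), n = nrow(G), q = ncol(G))
}

# Residual sum of squares of the least-squares fit on a column subset
# (ridge-stabilised solve, unpenalised intercept, RSS of the plain fit).
.rssCols <- function(eng, Gty, yty, cl) {
  Asub <- eng$A[cl, cl, drop = FALSE]
  pen <- rep(eng$pen, length(cl))
  pen[cl == 1L] <- 0
  ch <- tryCatch(chol(Asub + diag(pen, length(cl))),
                 error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf(
      "design rank-deficient beyond ridge rescue (condition number %.3g)",
      kappa(Asub)))
  b <- backsolve(ch, forwardsolve(t(ch), Gty[cl]))
  rss <- yty - 2 * sum(b * Gty[cl]) + sum(b * (Asub %*% b))
  list(rss = max(rss, 0), b = b, cols = cl)
}

#' One-sided F-test for a nested variance reduction
#'
#' Tests whether dropping `dfAdded` regressors (the source channel's block)
#' significantly inflates the residual sum of squares:
#' `stat = ((rssReduced - rssFull) / dfAdded) / (rssFull / (n - dfFull))`,
#' referred to the `F(dfAdded, n - dfFull)` distribution.
#'
#' @param rssFull,rssReduced residual sums of squares of the nested fits.
#' @param nSamples number of regression samples.
#' @param dfAdded number of columns dropped in the reduced model.
#' @param dfFull total number of full-model coefficients (intercept
#'   included).
#' @return one-sided p-value.
#' @export
#' @examples
#' significanceTest(10, 10, 100, 5, 11)   # no reduction -> p = 1
significanceTest <- function(rssFull, rssReduced, nSamples, dfAdded,
                             dfFull) {
  if (rssFull < 0 || rssReduced < 0) stop("RSS must be nonnegative")
  if (dfAdded < 1 || dfFull < 1) stop("degrees of freedom must be positive")
  if (nSamples <= dfFull) stop("need nSamples > dfFull")
  if (rssFull == 0) {
    warning("perfect fit: rssFull = 0")
    return(0)
  }
  stat <- max(0, (rssReduced - rssFull) / dfAdded) /
    (rssFull / (nSamples - dfFull))
  pf(stat, dfAdded, nSamples - dfFull, lower.tail = FALSE)
}

# Core per-pair computation given a prepared engine. Returns a GCResult.
.gcPairFromEngine <- function(eng, targets, target, source, alpha,
                              method, kernel, test = "ftest",
                              nPerm = 200L, permSeed = NULL,
                              crossCov = NA_real_,
                              labels = as.character(seq_len(ncol(targets)))) {
  y <- targets[, target]
  Gty <- crossprod(eng$G, y)
  yty <- sum(y^2)
  fullCols <- c(1L, unlist(eng$cols[eng$used]))
  redCols <- setdiff(fullCols, eng$cols[[source]])
  full <- .rssCols(eng, Gty, yty, fullCols)
  red <- .rssCols(eng, Gty, yty, redCols)
  n <- eng$n
  sigmaFull <- full$rss / n
  sigmaRed <- red$rss / n
  F <- if (sigmaFull <= 0) Inf else max(0, log(sigmaRed / sigmaFull))
  dfAdded <- length(eng$cols[[source]])
  dfFull <- length(fullCols)
  if (test == "permutation") {
    p <- .permPValue(eng, y, Gty, yty, fullCols, source, full$rss, red$rss,
                     nPerm, permSeed)
  } else {
    p <- significanceTest(full$rss, red$rss, n, dfAdded, dfFull)
  }
  new("GCResult", statistic = F, sigmaFull = sigmaFull,
      sigmaReduced = sigmaRed, crossCov = crossCov, pValue = p,
      decision = p < alpha, alpha = alpha,
      source = labels[source], target = labels[target],
      method = method, kernel = if (method == "ngcim") kernel else "",
      nSamples = as.integer(n), dfAdded = as.integer(dfAdded),
      dfFull = as.integer(dfFull))
}

# Circular-shift surrogate p-value: the source block's rows are rotated by a
# random offset (destroying any lagged alignment with the target while
# preserving the block's autocorrelation), the full model is refit, and the
# observed variance reduction is ranked among the surrogate reductions.
.permPValue <- function(eng, y, Gty, yty, fullCols, source, rssFull,
                        rssRed, nPerm, permSeed) {
  scl <- eng$cols[[source]]
  other <- setdiff(fullCols, scl)
  B <- eng$G[, scl, drop = FALSE]
  n <- eng$n
  Fobs <- log(max(rssRed, 1e-300) / max(rssFull, 1e-300))
  withSeed(permSeed, {
    offs <- sample.int(n - 2L, nPerm, replace = TRUE)
    hits <- 0L
    for (k in seq_len(nPerm)) {
      idx <- c((offs[k] + 1L):n, 1L:offs[k])
      Bs <- B[idx, , drop = FALSE]
      A <- eng$A
      A[scl, other] <- crossprod(Bs, eng$G[, other, drop = FALSE])
      A[other, scl] <- t(A[scl, other, drop = FALSE])
      Gty2 <- Gty
      Gty2[scl] <- crossprod(Bs, y)
      engP <- list(A = A, pen = eng$pen, n = n)
      rssP <- .rssCols(engP, Gty2, yty, fullCols)$rss
      Fp <- log(max(rssRed, 1e-300) / max(rssP, 1e-300))
      if (Fp >= Fobs) hits <- hits + 1L
    }
    (1 + hits) / (nPerm + 1)
  })
}

#' Conditional Granger causality for one directed pair
#'
#' Tests whether channel `source` improves the prediction of channel
#' `target` beyond the target's own past and the past of every other
#' channel (the conditioning set, which separates direct from indirect,
#' mediated influence). The full model regresses the target on the
#' intercept plus one predictor block per channel; the reduced model drops
#' the source's block with all remaining basis columns identical, so the
#' causality index `F = ln(sigma_reduced / sigma_full)` is nonnegative by
#' construction. With two channels the conditioning set is empty and the
#' test degrades to the ordinary pairwise test.
#'
#' For the nonlinear method (`"ngcim"`) each channel's lag block is expanded
#' in `p` radial basis functions (k-means centers, nearest-neighbour width);
#' the linear method (`"lgcim"`) uses the raw lag blocks, i.e. a vector
#' autoregression. Channels are z-scored before embedding, so decisions are
#' invariant to per-channel offset and positive scaling.
#'
#' @param series a [BinnedSeries-class] or a bins-by-channels matrix.
#' @param source,target channel indices (or names), source != target.
#' @param method `"ngcim"` (nonlinear, default) or `"lgcim"` (linear).
#' @param kernel RBF kernel for the nonlinear method, see [kernelValue()].
#' @param m model order (lags per channel); default 5 (50 ms at 10-ms bins,
#'   spanning synaptic and membrane timescales).
#' @param tau pure delay; default 0.
#' @param p RBF centers per channel block (capped at the number of distinct
#'   lag patterns); default 20.
#' @param alpha significance level of the presence decision; default 0.01.
#' @param seed integer seed for the clustering (and permutation, if used).
#' @param conditioning `"all"` (condition on every remaining channel,
#'   default) or `"none"` (pairwise test).
#' @param test `"ftest"` (parametric, default) or `"permutation"`
#'   (circular-shift surrogates of the source block).
#' @param nPerm surrogate count for the permutation test.
#' @return a [GCResult-class].
#' @export
#' @examples
#' fx <- makeFixture("chain3", duration = 20000, seed = 1)
#' conditionalGC(fx$series, source = 3, target = 2, seed = 1)
conditionalGC <- function(series, source, target,
                          method = c("ngcim", "lgcim"), kernel = "gf",
                          m = 5, tau = 0, p = 20, alpha = 0.01,
                          seed = NULL, conditioning = c("all", "none"),
                          test = c("ftest", "permutation"), nPerm = 200L) {
  method <- match.arg(method)
  conditioning <- match.arg(conditioning)
  test <- match.arg(test)
  mat <- if (is(series, "BinnedSeries")) seriesData(series)
         else as.matrix(series)
  labels <- if (!is.null(colnames(mat))) colnames(mat)
            else as.character(seq_len(ncol(mat)))
  if (is.character(source)) source <- match(source, labels)
  if (is.character(target)) target <- match(target, labels)
  if (is.na(source) || is.na(target) || source == target)
    stop("'source' and 'target' must be distinct valid channels")
  chans <- if (conditioning == "all") seq_len(ncol(mat))
           else c(target, source)
  bl <- .gcBlocks(mat[, chans, drop = FALSE], m, tau, method, kernel, p,
                  seed)
  src <- match(source, chans); tgt <- match(target, chans)
  if (bl$degenerate[src] || bl$degenerate[tgt])
    stop("degenerate (zero-variance) channel in the tested pair")
  eng <- .gcEngine(bl$blocks, which(!bl$degenerate))
  cc <- NA_real_
  if (length(eng$used) == 2L) cc <- .residCrossCov(eng, bl$targets, tgt, src)
  .gcPairFromEngine(eng, bl$targets, tgt, src, alpha, method, kernel,
                    test = test, nPerm = nPerm, permSeed = seed,
                    crossCov = cc, labels = labels[chans])
}

# Covariance of the full-model residuals of the two channels of a bivariate
# fit (the off-diagonal of the bivariate error covariance matrix; reported
# for completeness, not used in decisions).
.residCrossCov <- function(eng, targets, tgt, src) {
  fullCols <- c(1L, unlist(eng$cols[eng$used]))
  res <- lapply(c(tgt, src), function(ch) {
    y <- targets[, ch]
    f <- .rssCols(eng, crossprod(eng$G, y), sum(y^2), fullCols)
    drop(y - eng$G[, fullCols, drop = FALSE] %*% f$b)
  })
  cov(res[[1]], res[[2]])
}

#' Bivariate linear Granger causality, both directions
#'
#' Fits the two-variate vector autoregression of order `m` (full models:
#' each series on both pasts; reduced: each series on its own past only) and
#' returns the causality indices `F = ln(sigma_reduced / sigma_full)` with
#' F-test decisions for both directions, plus the covariance of the
#' full-model residuals.
#'
#' @param x,y numeric series of equal length (stationarity is the caller's
#'   responsibility).
#' @inheritParams conditionalGC
#' @return list with elements `yToX` and `xToY`, both [GCResult-class].
#' @export
#' @examples
#' set.seed(1)
#' y <- rnorm(500); x <- 0.8 * c(0, y[-500]) + rnorm(500)
#' linearGCPair(x, y)$yToX
linearGCPair <- function(x, y, m = 5, tau = 0, alpha = 0.01) {
  .gcPairBoth(cbind(x = x, y = y), "lgcim", "gf", m, tau, 0, alpha, NULL)
}

#' Bivariate nonlinear Granger causality, both directions
#'
#' As [linearGCPair()] but with each lag block expanded in radial basis
#' functions; the reduced model reuses the identical basis (same centers
#' and width) of the kept block, so nesting holds structurally.
#'
#' @inheritParams linearGCPair
#' @inheritParams conditionalGC
#' @export
#' @examples
#' set.seed(1)
#' y <- rnorm(400); x <- tanh(2 * c(0, y[-400])) + rnorm(400, sd = 0.25)
#' nonlinearGCPair(x, y, p = 8, seed = 1)$yToX
nonlinearGCPair <- function(x, y, m = 5, tau = 0, kernel = "gf", p = 20,
                            seed = NULL, alpha = 0.01) {
  .gcPairBoth(cbind(x = x, y = y), "ngcim", kernel, m, tau, p, alpha, seed)
}

.gcPairBoth <- function(mat, method, kernel, m, tau, p, alpha, seed) {
  if (length(unique(mat[, 1])) < 2L || length(unique(mat[, 2])) < 2L)
    stop("degenerate (zero-variance) channel")
  bl <- .gcBlocks(mat, m, tau, method, kernel, p, seed)
  if (any(bl$degenerate)) stop("degenerate (zero-variance) channel")
  eng <- .gcEngine(bl$blocks, 1:2)
  cc <- .residCrossCov(eng, bl$targets, 1L, 2L)
  labels <- colnames(mat)
  list(
    yToX = .gcPairFromEngine(eng, bl$targets, 1L, 2L, alpha, method,
                             kernel, crossCov = cc, labels = labels),
    xToY = .gcPairFromEngine(eng, bl$targets, 2L, 1L, alpha, method,
                             kernel, crossCov = cc, labels = labels))
}
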