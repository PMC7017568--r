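# Radial-basis-function regression: kernels, k-means centers, kNN width,
# minimum-square-error weights. These are the building blocks of the
# nonlinear Granger predictor: a channel's lagged past is expanded in p
# radial basis functions and the expansion enters an ordinary linear
# regression.

.kernelKinds <- c("gf", "rsf", "imqf")

#' Radial basis kernel value
#'
#' Evaluates the three supported radial kernels at distance `r` with shared
#' width `sigma`:
#' Gaussian `GF(r) = exp(-r^2 / (2 sigma^2))`;
#' reflected sigmoidal `RSF(r) = 1 / (1 + exp(r^2 / sigma^2))`;
#' inverse multiquadric `IMQF(r) = 1 / sqrt(r^2 + sigma^2)`.
#' All three are strictly decreasing in `r`.
#'
#' @param kind `"gf"`, `"rsf"` or `"imqf"` (case-insensitive).
#' @param r nonnegative distance(s).
#' @param sigma positive kernel width.
#' @return kernel value(s); in `(0, 1]` for GF, `(0, 1/2]` for RSF,
#'   `(0, 1/sigma]` for IMQF.
#' @export
#' @examples
#' kernelValue("gf", 0, 1)            # 1
#' kernelValue("rsf", 0, 2)           # 1/2
#' kernelValue("imqf", 0, 2)          # 1/2
kernelValue <- function(kind, r, sigma) {
  kind <- match.arg(tolower(kind), .kernelKinds)
  if (sigma <= 0) stop("'sigma' must be positive (parameter error)")
  if (any(r < 0)) stop("'r' must be nonnegative")
  switch(kind,
         gf   = exp(-r^2 / (2 * sigma^2)),
         rsf  = 1 / (1 + exp(r^2 / sigma^2)),
         imqf = 1 / sqrt(r^2 + sigma^2))
}

# Squared Euclidean distances between the rows of A and the rows of B.
.pairDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first center uniform, subsequent centers sampled
# proportionally to squared distance from the nearest chosen center.
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- .pairDist2(X, X[idx[1], , drop = FALSE])[, 1]
  if (k > 1) for (j in 2:k) {
    tot <- sum(d2)
    idx[j] <- if (tot <= 0) sample.int(n, 1L)
              else sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, .pairDist2(X, X[idx[j], , drop = FALSE])[, 1])
  }
  X[idx, , drop = FALSE]
}

#' Cluster lag vectors into RBF centers
#'
#' Finds `p` centers by k-means with k-means++ initialisation, Lloyd
#' iterations (max 300, restarted `nRestarts` times, best within-cluster sum
#' of squares kept). The run is deterministic given `seed`. When the data
#' hold exactly `p` distinct rows those rows are returned directly. For
#' large samples the clustering operates on a seeded subsample of
#' `maxPoints` rows; for binarised spike embeddings (at most `2^m` distinct
#' patterns) this is lossless in practice.
#'
#' @param data numeric matrix, one lag vector per row.
#' @param p number of centers; must not exceed the number of distinct rows.
#' @param seed integer seed.
#' @param nRestarts k-means restarts (default 5).
#' @param maxIter Lloyd iteration cap (default 300).
#' @param maxPoints clustering subsample cap (default 2000).
#' @return a `p x ncol(data)` matrix of centers.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 10), 30))
#' fitCenters(X, 2, seed = 1)
fitCenters <- function(data, p, seed = NULL, nRestarts = 5L,
                       maxIter = 300L, maxPoints = 2000L) {
  data <- as.matrix(data)
  if (p < 1) stop("'p' must be >= 1")
  u <- unique(data)
  if (p > nrow(u))
    stop("degeneracy: 'p' exceeds the number of distinct data vectors (",
         nrow(u), "); lower p")
  if (p == nrow(u)) {
    o <- do.call(order, as.data.frame(u))
    return(u[o, , drop = FALSE])
  }
  withSeed(seed, {
    X <- if (nrow(data) > maxPoints)
      data[sample.int(nrow(data), maxPoints), , drop = FALSE] else data
    # the subsample must still carry at least p distinct rows
    if (nrow(unique(X)) < p) X <- u
    best <- NULL
    for (r in seq_len(nRestarts)) {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = .kmeansppInit(X, p),
                                       iter.max = maxIter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best))
      stop("k-means failed on all restarts; data too degenerate for p = ", p)
    unname(best$centers)
  })
}

#' Kernel width from nearest-neighbour distances between centers
#'
#' The shared RBF width `sigma` is the mean, over centers, of the average
#' distance from each center to its `kNN` nearest other centers (`kNN`
#' clipped to `p - 1`). Homogeneous of degree 1: scaling all centers by `c`
#' scales `sigma` by `c`.
#'
#' @param centers matrix of centers, one per row (>= 2 rows).
#' @param kNN number of neighbours (default 2).
#' @return positive width; if all centers coincide, a floor of `1e-6` is
#'   returned with a warning.
#' @export
#' @examples
#' estimateWidth(matrix(c(0, 1, 3)), kNN = 1)   # mean(1, 1, 2) = 4/3
estimateWidth <- function(centers, kNN = 2L) {
  centers <- as.matrix(centers)
  p <- nrow(centers)
  if (p < 2) stop("need at least 2 centers")
  kNN <- max(1L, min(as.integer(kNN), p - 1L))
  d <- sqrt(.pairDist2(centers, centers))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(v) mean(sort(v)[seq_len(kNN)]))
  sigma <- mean(nn)
  if (!is.finite(sigma) || sigma <= 1e-12) {
    warning("centers coincide; falling back to sigma = 1e-6")
    sigma <- 1e-6
  }
  sigma
}

#' Evaluate an RBF basis matrix
#'
#' Returns the `n x p` matrix of kernel evaluations
#' `Phi[k, rho] = kernel(||X_k - center_rho||, sigma)`.
#'
#' @param data matrix of lag vectors (rows).
#' @param centers matrix of centers (rows), same column count.
#' @param sigma shared width.
#' @param kind kernel kind, see [kernelValue()].
#' @return basis evaluation matrix.
#' @export
rbfBasis <- function(data, centers, sigma, kind = "gf") {
  data <- as.matrix(data); centers <- as.matrix(centers)
  if (ncol(data) != ncol(centers))
    stop("'data' and 'centers' must have the same dimension")
  r <- sqrt(.pairDist2(data, centers))
  kernelValue(kind, r, sigma)
}

#' Minimum-square-error output weights
#'
#' Solves the output layer of the RBF regression by least squares on the
#' given design matrix (first column expected to be the intercept), with a
#' small relative ridge `lambda * mean(diag(X'X))` on the non-intercept
#' coefficients for numerical stability on near-degenerate designs.
#'
#' @param design `n x q` design matrix including an intercept column.
#' @param targets numeric response vector of length `n`.
#' @param lambda relative ridge penalty (default `1e-8`).
#' @return list with `weights` (length q) and `residualVariance`
#'   (mean squared residual).
#' @export
#' @examples
#' X <- cbind(1, rnorm(100))
#' y <- 2 + 3 * X[, 2] + rnorm(100, sd = 0.1)
#' fitWeights(X, y)$weights
fitWeights <- function(design, targets, lambda = 1e-8) {
  design <- as.matrix(design)
  n <- nrow(design); q <- ncol(design)
  if (n < q) stop("need at least as many rows as columns")
  if (length(targets) != n) stop("length(targets) must equal nrow(design)")
  A <- crossprod(design)
  pen <- rep(lambda * mean(diag(A)), q)
  pen[1] <- 0                       # intercept unpenalised
  ch <- tryCatch(chol(A + diag(pen, q)), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf(
      "design is rank-deficient beyond ridge rescue (condition number %.3g)",
      kappa(A)))
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(design, targets)))
  res <- targets - design %*% b
  list(weights = drop(b), residualVariance = mean(res^2))
}

#' Fit a full RBF regression model
#'
#' Convenience wrapper chaining the learning pipeline: k-means centers
#' ([fitCenters()]), nearest-neighbour width ([estimateWidth()]), basis
#' evaluation ([rbfBasis()]) and minimum-square-error weights
#' ([fitWeights()]), with an intercept.
#'
#' @param data matrix of predictor lag vectors.
#' @param targets response vector.
#' @param p number of centers.
#' @param kind kernel kind.
#' @param seed integer seed for the clustering.
#' @param kNN width rule neighbours.
#' @return list with `kind`, `centers`, `sigma`, `weights`,
#'   `residualVariance`.
#' @export
rbfFit <- function(data, targets, p, kind = "gf", seed = NULL, kNN = 2L) {
  centers <- fitCenters(data, p, seed = seed)
  sigma <- if (nrow(centers) >= 2) estimateWidth(centers, kNN) else 1
  Phi <- rbfBasis(data, centers, sigma, kind)
  fit <- fitWeights(cbind(1, Phi), targets)
  list(kind = kind, centers = centers, sigma = sigma,
       weights = fit$weights, residualVariance = fit$residualVariance)
}
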