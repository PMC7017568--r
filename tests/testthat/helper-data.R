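# In-code fixtures shared across test files.

# Bivariate series with a known linear lag-1 coupling y -> x.
simCoupled <- function(N, coef = 0.8, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rnorm(N)
  x <- coef * c(0, y[-N]) + rnorm(N, sd = sd)
  list(x = x, y = y)
}

# Independent white-noise pair (null instance).
simNull <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(x = rnorm(N), y = rnorm(N))
}

# Brute-force OLS via explicit normal equations: returns the residual sum
# of squares of regressing y on cbind(1, X). Kept independent of the
# package's solver path on purpose.
oracleRSS <- function(X, y) {
  D <- cbind(1, X)
  b <- solve(t(D) %*% D, t(D) %*% y)
  sum((y - D %*% b)^2)
}

# Oracle for the bivariate linear Granger index F_{y->x}: z-score, embed,
# fit full and reduced models by explicit normal equations.
oracleLinearF <- function(x, y, m = 5, tau = 0) {
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  N <- length(x)
  nEff <- N - m - tau
  tx <- zx[seq_len(nEff) + m + tau]
  LX <- sapply(seq_len(m), function(l) zx[seq_len(nEff) + m - l])
  LY <- sapply(seq_len(m), function(l) zy[seq_len(nEff) + m - l])
  full <- oracleRSS(cbind(LX, LY), tx)
  red <- oracleRSS(LX, tx)
  list(F = log(red / full), sigmaFull = full / nEff,
       sigmaReduced = red / nEff, nEff = nEff)
}
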