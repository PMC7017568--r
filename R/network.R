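# Random directed network generation and synaptic weight assignment.
#
# Adjacency matrices follow the "column acts row" convention throughout:
# B[i, j] = 1 means neuron j (column) drives neuron i (row).

#' Generate a random sparse directed network
#'
#' Draws a binary adjacency matrix B in the column-acts-row convention
#' (`B[i, j] = 1` means neuron j drives neuron i). Each off-diagonal ordered
#' pair receives an edge independently with probability `connectionRatio`;
#' the diagonal is zero (no self-connections). With `exactCount = TRUE` the
#' realised edge count is fixed to `round(connectionRatio * n * (n - 1))`
#' instead, placed uniformly at random.
#'
#' @param n number of nodes (>= 2).
#' @param connectionRatio probability of each directed off-diagonal edge,
#'   in `[0, 1]`; default 0.2 (sparse, biologically motivated).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param exactCount fix the total edge count instead of the per-edge
#'   probability.
#' @return an `n x n` binary matrix.
#' @export
#' @examples
#' B <- generateRandomNetwork(6, 0.2, seed = 1)
#' sum(B)   # about 0.2 * 30 edges
generateRandomNetwork <- function(n, connectionRatio = 0.2, seed = NULL,
                                  exactCount = FALSE) {
  if (length(n) != 1L || n < 2)
    stop("'n' must be a single integer >= 2")
  n <- as.integer(n)
  if (connectionRatio < 0 || connectionRatio > 1)
    stop("'connectionRatio' must be in [0, 1]")
  withSeed(seed, {
    B <- matrix(0L, n, n)
    off <- which(row(B) != col(B))
    if (exactCount) {
      k <- round(connectionRatio * length(off))
      if (k > 0) B[sample(off, k)] <- 1L
    } else {
      B[off] <- as.integer(runif(length(off)) < connectionRatio)
    }
    B
  })
}

#' Assign synaptic weights to a binary adjacency matrix
#'
#' Every existing connection receives the same positive (excitatory) weight;
#' absent connections and the diagonal stay zero.
#'
#' @param B binary adjacency matrix (column-acts-row).
#' @param weight synaptic strength shared by all edges; the default is
#'   calibrated so that one presynaptic spike detectably raises the
#'   postsynaptic firing probability within about two 10-ms bins.
#' @return numeric weight matrix of the same shape.
#' @export
makeWeightMatrix <- function(B, weight = 2) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stop("'B' must be square")
  if (any(diag(B) != 0)) stop("'B' must have a zero diagonal")
  if (any(!B %in% c(0, 1))) stop("'B' must be binary")
  if (weight <= 0) stop("'weight' must be positive")
  W <- B * weight
  storage.mode(W) <- "double"
  W
}

#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow `tau_m dV/dt = E_m - V + R_m I(t)` with
#' threshold-and-reset spiking: when V crosses `vTh` a spike is emitted,
#' V is reset to `vReset` and held there for the absolute refractory period
#' `tRef`. `I(t)` is the sum of synaptic currents (unit-height exponential
#' kernel with decay `tauS`) plus an independent Gaussian background current
#' per neuron per step.
#'
#' The defaults are textbook values (resting potential -70 mV, threshold
#' -54 mV, reset -80 mV, membrane time constant 20 ms) with the background
#' drive calibrated so an isolated neuron fires at roughly 5-20 Hz.
#' `noiseSd` is expressed per square-root millisecond: the per-step deviate
#' is `noiseSd / sqrt(dt)`, so the integrated drive does not change when the
#' integration step is refined.
#'
#' @param tauM membrane time constant (ms).
#' @param rM membrane resistance (arbitrary resistance units).
#' @param cM membrane capacitance; must satisfy `tauM = rM * cM`.
#' @param eM resting potential (mV).
#' @param vTh firing threshold (mV).
#' @param vReset post-spike reset potential (mV).
#' @param tRef absolute refractory period (ms).
#' @param tauS synaptic decay time constant (ms).
#' @param noiseMean mean background current.
#' @param noiseSd background current standard deviation (per sqrt(ms)).
#' @return a classed list of validated parameters.
#' @export
#' @examples
#' p <- neuronParams()
#' p$tauM
neuronParams <- function(tauM = 20, rM = 10, cM = tauM / rM,
                         eM = -70, vTh = -54, vReset = -80,
                         tRef = 2, tauS = 5,
                         noiseMean = 1.25, noiseSd = 2.2) {
  if (abs(tauM - rM * cM) > 1e-8 * max(1, abs(tauM)))
    stop("'tauM' must equal rM * cM")
  if (!(vReset <= eM && eM < vTh))
    stop("need vReset <= eM < vTh")
  if (tauS <= 0) stop("'tauS' must be positive")
  if (tRef < 0) stop("'tRef' must be nonnegative")
  if (noiseSd < 0) stop("'noiseSd' must be nonnegative")
  structure(list(tauM = tauM, rM = rM, cM = cM, eM = eM, vTh = vTh,
                 vReset = vReset, tRef = tRef, tauS = tauS,
                 noiseMean = noiseMean, noiseSd = noiseSd),
            class = "neuronParams")
}

# Evaluate a block of code with a temporary RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-task seed mixer: fold a sequence of integers into a
# master seed with the multiplicative-congruential step x <- (48271 x + k)
# mod (2^31 - 1). All arithmetic stays below 2^53 so it is exact in doubles.
#' Derive a reproducible sub-seed from a master seed
#'
#' Folds a vector of nonnegative integers (e.g. round, network size, network
#' index) into `master` so that any single task of a large experiment can be
#' re-run in isolation with the same seed.
#'
#' @param master master seed (nonnegative integer).
#' @param keys integer vector identifying the task.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' mixSeed(42, c(1, 6, 17))
mixSeed <- function(master, keys) {
  m <- 2147483647
  h <- as.double(master) %% m
  for (k in c(as.double(keys), 1)) {
    h <- (48271 * h + (k %% m)) %% m
  }
  as.integer(max(1, h %% (m - 1)))
}
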