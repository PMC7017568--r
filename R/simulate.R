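# Leaky integrate-and-fire network simulation and spike binning.

#' Simulate a leaky integrate-and-fire network
#'
#' Integrates `tau_m dV_i/dt = E_m - V_i + R_m I_i(t)` for every neuron by
#' forward Euler. The input current `I_i(t)` is the weighted sum of
#' presynaptic spike traces, `sum_j w_ij sum_f alpha(t - t_j^(f))` with
#' `alpha(s) = exp(-s / tau_s)` for `s >= 0`, plus independent Gaussian
#' background noise per neuron per step. When `V_i` reaches the threshold a
#' spike is recorded, `V_i` is reset and held for the refractory period.
#' Synaptic transmission carries a one-step (`dt`) delay: a spike first
#' drives its targets on the following integration step.
#'
#' All neurons start at the resting potential. The simulation is
#' deterministic given `seed`.
#'
#' @param W weight matrix in column-acts-row convention (`W[i, j]` is the
#'   strength of j -> i); use [makeWeightMatrix()] to build one from a binary
#'   adjacency. A binary matrix is accepted and scaled by the default weight.
#' @param params a [neuronParams()] list.
#' @param duration simulated time (ms); default 100 s.
#' @param dt Euler step (ms); must satisfy `dt <= tauS / 2` and
#'   `dt <= tauM / 2` for stability.
#' @param seed integer seed for the background noise.
#' @param v0 initial membrane potential (mV); defaults to the resting
#'   potential.
#' @param returnVoltage also record the per-step membrane potentials
#'   (attribute `"voltage"`, a steps-by-neurons matrix). Meant for short
#'   diagnostic runs; memory grows with `duration / dt`.
#' @return a [SpikeRaster-class].
#' @export
#' @examples
#' B <- generateRandomNetwork(3, 0.3, seed = 7)
#' r <- simulateNetwork(makeWeightMatrix(B), duration = 2000, seed = 7)
#' r
simulateNetwork <- function(W, params = neuronParams(), duration = 1e5,
                            dt = 1, seed = NULL, v0 = NULL,
                            returnVoltage = FALSE) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("'W' must be square (dimension error)")
  if (!inherits(params, "neuronParams"))
    stop("'params' must come from neuronParams()")
  if (duration <= 0) stop("'duration' must be positive")
  if (dt > params$tauS / 2 || dt > params$tauM / 2)
    stop("unstable step: need dt <= tauS/2 and dt <= tauM/2")
  if (all(W %in% c(0, 1)) && any(W == 1)) W <- makeWeightMatrix(W)
  storage.mode(W) <- "double"
  if (is.null(v0)) v0 <- params$eM
  out <- withSeed(seed,
    .lif_simulate_cpp(W, duration, dt, params$tauM, params$eM, params$rM,
                      params$vTh, params$vReset, params$tRef, params$tauS,
                      params$noiseMean, params$noiseSd, v0, returnVoltage))
  r <- SpikeRaster(out$spikes, duration = duration, dt = dt)
  if (returnVoltage) attr(r, "voltage") <- out$voltage
  r
}

#' Synaptic current driven by a spike raster
#'
#' Closed-form evaluation of the synaptic input to neuron `i` at time `t`:
#' `I_i(t) = sum_j w_ij sum_f alpha(t - t_j^(f))` with unit-height
#' exponential kernel `alpha(s) = exp(-s / tauS)` for `s >= 0` and 0
#' otherwise (so a spike arriving exactly at `t` contributes its full
#' weight). Spikes after `t` contribute nothing; an empty history gives 0.
#'
#' @param t evaluation time (ms).
#' @param i postsynaptic neuron index.
#' @param W weight matrix (column-acts-row).
#' @param raster a [SpikeRaster-class] of presynaptic activity.
#' @param tauS synaptic decay constant (ms).
#' @return the current value (nonnegative for nonnegative weights).
#' @export
#' @examples
#' r <- SpikeRaster(list(c(5, 10)), duration = 20)
#' synapticCurrent(15, 1, matrix(1, 1, 1), r, tauS = 5)
synapticCurrent <- function(t, i, W, raster, tauS = 5) {
  if (t < 0) stop("'t' must be nonnegative")
  W <- as.matrix(W)
  stopifnot(i >= 1, i <= nrow(W))
  total <- 0
  st <- spikeTimes(raster)
  for (j in seq_len(ncol(W))) {
    w <- W[i, j]
    if (w == 0) next
    s <- t - st[[j]]
    s <- s[s >= 0]
    if (length(s)) total <- total + w * sum(exp(-s / tauS))
  }
  total
}

#' Bin a spike raster into a multichannel series
#'
#' Bin `b` (0-based, half-open `[b * binWidth, (b + 1) * binWidth)`) of
#' neuron j holds the number of spikes of j in that interval (`mode =
#' "count"`) or 1 if there was at least one (`mode = "indicator"`, the
#' default, matching pulse-sequence sampling at 10 ms). Only complete bins
#' are kept: `T = floor(duration / binWidth)`. Count mode conserves total
#' spike counts of spikes falling in complete bins.
#'
#' @param raster a [SpikeRaster-class].
#' @param binWidth bin width (ms), default 10.
#' @param mode `"indicator"` or `"count"`.
#' @return a [BinnedSeries-class].
#' @export
#' @examples
#' r <- SpikeRaster(list(c(3, 12, 19)), duration = 30)
#' seriesData(binSpikes(r, 10, mode = "count"))
binSpikes <- function(raster, binWidth = 10,
                      mode = c("indicator", "count")) {
  mode <- match.arg(mode)
  if (binWidth <= 0) stop("'binWidth' must be positive")
  nb <- floor(duration(raster) / binWidth)
  st <- spikeTimes(raster)
  out <- matrix(0, nrow = nb, ncol = length(st))
  for (j in seq_along(st)) {
    b <- floor(st[[j]] / binWidth) + 1
    # a spike at exactly duration (= right edge of the last complete bin
    # when duration is a multiple of binWidth) is kept in the last bin
    b[st[[j]] == nb * binWidth] <- nb
    b <- b[b >= 1 & b <= nb]
    if (length(b)) {
      tb <- tabulate(b, nbins = nb)
      out[, j] <- if (mode == "count") tb else pmin(tb, 1)
    }
  }
  BinnedSeries(out, binWidth = binWidth)
}
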