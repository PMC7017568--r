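#' @import methods
#' @importFrom stats kmeans pf rnorm runif sd var cov quantile
#' @importFrom utils head
#' @importFrom Rcpp evalCpp
#' @useDynLib spikegc, .registration = TRUE
NULL

#' Multichannel spike raster
#'
#' Per-neuron spike times produced by [simulateNetwork()]. Times are in
#' milliseconds from simulation onset; each neuron's times are sorted and lie
#' in `[0, duration]`.
#'
#' @slot spikeTimes list of numeric vectors, one per neuron (ms).
#' @slot duration total simulated time (ms).
#' @slot dt integration step used to produce the raster (ms).
#'
#' @seealso [binSpikes()], [spikeTimes()], [nNeurons()]
#' @exportClass SpikeRaster
setClass("SpikeRaster",
         representation(spikeTimes = "list", duration = "numeric",
                        dt = "numeric"))

setValidity("SpikeRaster", function(object) {
  msg <- character()
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "'duration' must be a single positive number")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  for (i in seq_along(object@spikeTimes)) {
    st <- object@spikeTimes[[i]]
    if (!is.numeric(st))
      msg <- c(msg, sprintf("spikeTimes[[%d]] is not numeric", i))
    else {
      if (is.unsorted(st))
        msg <- c(msg, sprintf("spikeTimes[[%d]] is not sorted", i))
      if (length(st) && (min(st) < 0 || max(st) > object@duration))
        msg <- c(msg, sprintf("spikeTimes[[%d]] outside [0, duration]", i))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Binned multichannel series
#'
#' Spike trains discretised into fixed-width time bins: a `T x n` matrix of
#' per-bin spike indicators (0/1) or counts, one column per neuron. This is
#' the input format of the Granger-causality identification functions.
#'
#' @slot data numeric matrix, bins in rows, channels in columns;
#'   nonnegative integers.
#' @slot binWidth bin width (ms).
#' @slot channelIds character vector of channel names.
#'
#' @seealso [binSpikes()], [seriesData()], [readSeries()]
#' @exportClass BinnedSeries
setClass("BinnedSeries",
         representation(data = "matrix", binWidth = "numeric",
                        channelIds = "character"))

setValidity("BinnedSeries", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "'data' must be a numeric matrix")
  else {
    if (any(d < 0) || any(d != round(d)))
      msg <- c(msg, "'data' entries must be nonnegative integers")
  }
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "'binWidth' must be a single positive number")
  if (ncol(d) != length(object@channelIds))
    msg <- c(msg, "length(channelIds) must equal ncol(data)")
  if (length(msg)) msg else TRUE
})

#' Granger-causality test result for one directed pair
#'
#' Holds the residual variances of the full and reduced regressions, the
#' causality index `F = ln(sigmaReduced / sigmaFull)`, the significance of
#' the variance reduction, and the resulting presence/absence decision for
#' the directed influence source -> target.
#'
#' @slot statistic causality index F (>= 0 under the shared-basis nesting).
#' @slot sigmaFull residual variance of the full model (source included).
#' @slot sigmaReduced residual variance of the reduced model (source removed).
#' @slot crossCov covariance of the full-model residuals of the two channels
#'   of a bivariate fit (`NA` for conditional fits); reported, not used in
#'   decisions.
#' @slot pValue one-sided F-test (or permutation) p-value.
#' @slot decision logical; `TRUE` when pValue < alpha.
#' @slot alpha significance level used for the decision.
#' @slot source,target channel labels.
#' @slot method `"lgcim"` or `"ngcim"`.
#' @slot kernel RBF kernel used (`""` for the linear method).
#' @slot nSamples usable sample count of the regressions.
#' @slot dfAdded,dfFull added and total regression degrees of freedom.
#'
#' @seealso [conditionalGC()], [linearGCPair()], [nonlinearGCPair()]
#' @exportClass GCResult
setClass("GCResult",
         representation(statistic = "numeric", sigmaFull = "numeric",
                        sigmaReduced = "numeric", crossCov = "numeric",
                        pValue = "numeric", decision = "logical",
                        alpha = "numeric", source = "character",
                        target = "character", method = "character",
                        kernel = "character", nSamples = "integer",
                        dfAdded = "integer", dfFull = "integer"))

setValidity("GCResult", function(object) {
  msg <- character()
  if (object@sigmaFull < 0 || object@sigmaReduced < 0)
    msg <- c(msg, "residual variances must be nonnegative")
  if (object@statistic < 0)
    msg <- c(msg, "causality index must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpikeRaster", function(object) {
  ns <- vapply(object@spikeTimes, length, 1L)
  cat(sprintf("SpikeRaster: %d neurons, %.0f ms (dt = %g ms)\n",
              length(ns), object@duration, object@dt))
  cat(sprintf("  spikes per neuron: %s (mean rate %.1f Hz)\n",
              paste(head(ns, 8L), collapse = ", "),
              mean(ns) / object@duration * 1000))
})

setMethod("show", "BinnedSeries", function(object) {
  cat(sprintf("BinnedSeries: %d bins x %d channels (bin width %g ms)\n",
              nrow(object@data), ncol(object@data), object@binWidth))
  cat(sprintf("  channels: %s\n",
              paste(head(object@channelIds, 8L), collapse = ", ")))
})

setMethod("show", "GCResult", function(object) {
  lab <- if (object@method == "ngcim")
    sprintf("nonlinear (%s kernel)", object@kernel) else "linear"
  cat(sprintf("GCResult: %s -> %s, %s conditional Granger causality\n",
              object@source, object@target, lab))
  cat(sprintf("  F = %.5g  (sigma_reduced = %.5g, sigma_full = %.5g)\n",
              object@statistic, object@sigmaReduced, object@sigmaFull))
  cat(sprintf("  p = %.3g at alpha = %g -> connection %s\n",
              object@pValue, object@alpha,
              if (object@decision) "PRESENT" else "absent"))
})

#' Accessors for spikegc objects
#'
#' @param x a [SpikeRaster-class], [BinnedSeries-class] or
#'   [GCResult-class] object.
#' @return `spikeTimes`: list of per-neuron spike times (ms); `duration`:
#'   simulated time (ms); `nNeurons`/`nChannels`: object dimensions;
#'   `seriesData`: the bins-by-channels matrix; `binWidth`: bin width (ms);
#'   `channelIds`: channel labels; `causalityIndex`, `pValue`, `decision`:
#'   the test summary of a `GCResult`.
#' @name accessors
#' @aliases spikeTimes duration nNeurons seriesData binWidth channelIds
#'   nChannels nBins causalityIndex pValue decision
#' @examples
#' r <- SpikeRaster(list(c(3, 12, 19), numeric(0)), duration = 30)
#' nNeurons(r)
#' spikeTimes(r)[[1]]
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("causalityIndex", function(x) standardGeneric("causalityIndex"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

#' @rdname accessors
setMethod("spikeTimes", "SpikeRaster", function(x) x@spikeTimes)
#' @rdname accessors
setMethod("duration", "SpikeRaster", function(x) x@duration)
#' @rdname accessors
setMethod("nNeurons", "SpikeRaster", function(x) length(x@spikeTimes))
#' @rdname accessors
setMethod("seriesData", "BinnedSeries", function(x) x@data)
#' @rdname accessors
setMethod("binWidth", "BinnedSeries", function(x) x@binWidth)
#' @rdname accessors
setMethod("channelIds", "BinnedSeries", function(x) x@channelIds)
#' @rdname accessors
setMethod("nChannels", "BinnedSeries", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nBins", "BinnedSeries", function(x) nrow(x@data))
#' @rdname accessors
setMethod("causalityIndex", "GCResult", function(x) x@statistic)
#' @rdname accessors
setMethod("pValue", "GCResult", function(x) x@pValue)
#' @rdname accessors
setMethod("decision", "GCResult", function(x) x@decision)

#' Construct a SpikeRaster
#'
#' @param spikeTimes list of numeric vectors of spike times (ms), one per
#'   neuron.
#' @param duration total recorded time (ms).
#' @param dt integration step that produced the raster (ms); purely
#'   informational for hand-built rasters.
#' @return a [SpikeRaster-class] object.
#' @export
#' @examples
#' SpikeRaster(list(c(3, 12, 19), c(5)), duration = 30)
SpikeRaster <- function(spikeTimes, duration, dt = 1) {
  spikeTimes <- lapply(spikeTimes, function(v) sort(as.numeric(v)))
  new("SpikeRaster", spikeTimes = spikeTimes,
      duration = as.numeric(duration), dt = as.numeric(dt))
}

#' Construct a BinnedSeries
#'
#' @param data bins-by-channels matrix of nonnegative integers.
#' @param binWidth bin width (ms), default 10.
#' @param channelIds channel labels; defaults to existing column names or
#'   `"n1"`, `"n2"`, ...
#' @return a [BinnedSeries-class] object.
#' @export
#' @examples
#' BinnedSeries(matrix(rbinom(40, 1, 0.2), 20, 2))
BinnedSeries <- function(data, binWidth = 10, channelIds = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelIds))
    channelIds <- if (!is.null(colnames(data))) colnames(data)
                  else paste0("n", seq_len(ncol(data)))
  colnames(data) <- channelIds
  new("BinnedSeries", data = data, binWidth = as.numeric(binWidth),
      channelIds = as.character(channelIds))
}
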