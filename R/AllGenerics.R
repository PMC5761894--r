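#' Number of islets in a tissue
#' @param x a [Tissue-class]
#' @return integer islet count
#' @export
setGeneric("nIslets", function(x) standardGeneric("nIslets"))

#' Beta-cell count of a tissue or run
#' @param x a [Tissue-class]
#' @return integer number of live Beta cells
#' @export
setGeneric("betaCount", function(x) standardGeneric("betaCount"))

#' Per-day time series of a run
#' @param x a [SimulationRun-class]
#' @return data.frame of per-day counts
#' @export
setGeneric("series", function(x) standardGeneric("series"))

#' Total event counts of a run
#' @param x a [SimulationRun-class]
#' @return named numeric vector
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' First day of 50\% median Beta-cell loss
#'
#' The first recorded day at which the cross-replicate median Beta-cell count
#' falls to half the median initial count.
#'
#' @param x a [SimEnsemble-class] or a list of per-replicate series
#'   data.frames.
#' @param ... further arguments.
#' @return day (numeric) or `NA` if never reached
#' @export
setGeneric("halfLossDay", function(x, ...) standardGeneric("halfLossDay"))

#' Inflammation window of an ensemble
#'
#' Onset is the first day the median Beta count drops below 95\% of the median
#' initial count; the end is the first subsequent day after which the median
#' changes by less than 1\% of the initial count over the following five days.
#'
#' @param x a [SimEnsemble-class] or list of series data.frames.
#' @param ... threshold overrides (`onsetFrac`, `flatFrac`, `flatDays`).
#' @return named numeric `c(onset, end)` or `NA` if no onset
#' @export
setGeneric("inflammationWindow",
           function(x, ...) standardGeneric("inflammationWindow"))

#' Per-day box-plot summary of an ensemble
#'
#' Quartiles use linear interpolation; whiskers are the most extreme values
#' within 1.5 IQR fences; values beyond the fences count as outliers.
#'
#' @param x a [SimEnsemble-class] or list of series data.frames.
#' @param ... passed on (`what` selects the cell type column).
#' @return data.frame of per-day `q1`, `median`, `q3`, `whiskerLow`,
#'   `whiskerHigh`, `nOutliers`
#' @export
setGeneric("quartileSummary",
           function(x, ...) standardGeneric("quartileSummary"))

#' Full ensemble summary across all cell types
#' @param x a [SimEnsemble-class]
#' @param ... unused
#' @return data.frame of per-day box statistics, one block per cell type
#' @export
setGeneric("summarizeEnsemble",
           function(x, ...) standardGeneric("summarizeEnsemble"))
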