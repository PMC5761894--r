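# list of per-replicate series from either representation
.seriesList <- function(x) {
  if (is(x, "SimEnsemble")) x@runs
  else if (is.list(x) && all(vapply(x, is.data.frame, logical(1)))) x
  else stop("expected a SimEnsemble or a list of series data.frames")
}

# days x replicates matrix of one column
.seriesMatrix <- function(runs, what = "beta") {
  stopifnot(length(runs) >= 1)
  days <- runs[[1]]$day
  for (r in runs)
    if (!identical(r$day, days))
      stop("replicates do not share a common day grid")
  m <- vapply(runs, function(r) r[[what]], numeric(length(days)))
  m <- matrix(m, nrow = length(days))
  rownames(m) <- days
  m
}

#' Cross-replicate count matrix
#'
#' @param x a [SimEnsemble-class] or list of series data.frames
#' @param what column to extract (`"beta"`, `"naive"`, `"effector"`,
#'   `"memory"`)
#' @return numeric matrix, days in rows and replicates in columns
#' @export
ensembleMatrix <- function(x, what = "beta") {
  .seriesMatrix(.seriesList(x), what)
}

.boxStats <- function(v) {
  # linear-interpolation quantiles (R type 7)
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  c(q1 = q[1], median = q[2], q3 = q[3],
    whiskerLow = min(inside), whiskerHigh = max(inside),
    nOutliers = sum(v < lo | v > hi))
}

#' @describeIn quartileSummary box statistics per day for one cell type
#' @param what cell-type column (`"beta"` by default)
#' @param day optional subset of days
#' @export
setMethod("quartileSummary", "ANY", function(x, what = "beta", day = NULL) {
  runs <- .seriesList(x)
  if (length(runs) < 2)
    stop("quartile summaries need at least 2 replicates")
  m <- .seriesMatrix(runs, what)
  days <- runs[[1]]$day
  if (!is.null(day)) {
    keep <- days %in% day
    if (!any(keep)) stop("requested day not in the recorded series")
    m <- m[keep, , drop = FALSE]
    days <- days[keep]
  }
  stats <- t(apply(m, 1, .boxStats))
  out <- data.frame(day = days, stats, row.names = NULL)
  out$nOutliers <- as.integer(out$nOutliers)
  out
})

#' Box statistics of one sample
#'
#' Quartiles by linear interpolation, whiskers at the most extreme values
#' within the 1.5 IQR fences, and the count of outliers beyond them.
#'
#' @param counts numeric vector (e.g. one day's counts across replicates)
#' @return named numeric: `q1`, `median`, `q3`, `whiskerLow`, `whiskerHigh`,
#'   `nOutliers`
#' @examples
#' boxStats(c(1, 2, 3, 4, 5))
#' @export
boxStats <- function(counts) {
  if (length(counts) == 0) stop("empty sample")
  .boxStats(counts)
}

.medianSeries <- function(runs, what = "beta") {
  m <- .seriesMatrix(runs, what)
  apply(m, 1, median)
}

.halfLossFromMedians <- function(days, med, frac = 0.5) {
  idx <- which(med <= frac * med[1])
  if (length(idx) == 0) return(NA_real_)
  days[idx[1]]
}

#' @describeIn halfLossDay first day the median Beta count is at or below
#'   half the median initial count
#' @export
setMethod("halfLossDay", "ANY", function(x, ...) {
  runs <- .seriesList(x)
  med <- .medianSeries(runs, "beta")
  .halfLossFromMedians(runs[[1]]$day, med)
})

#' @describeIn inflammationWindow window from the ensemble median Beta series
#' @param onsetFrac onset threshold as a fraction of the initial median (0.95)
#' @param flatFrac flatness threshold as a fraction of the initial median (0.01)
#' @param flatDays number of following days required to stay flat (5)
#' @export
setMethod("inflammationWindow", "ANY",
          function(x, onsetFrac = 0.95, flatFrac = 0.01, flatDays = 5) {
  runs <- .seriesList(x)
  days <- runs[[1]]$day
  med <- .medianSeries(runs, "beta")
  init <- med[1]
  onsetIdx <- which(med < onsetFrac * init)
  if (length(onsetIdx) == 0) return(NA)
  onsetIdx <- onsetIdx[1]
  endIdx <- NA_integer_
  for (i in seq(onsetIdx, length(med))) {
    ahead <- seq(i + 1, min(i + flatDays, length(med)))
    if (length(ahead) == 0 || max(ahead) > length(med)) break
    if (all(abs(med[ahead] - med[i]) < flatFrac * init)) { endIdx <- i; break }
  }
  if (is.na(endIdx)) return(NA)
  c(onset = days[onsetIdx], end = days[endIdx])
})

#' @describeIn summarizeEnsemble per-day box statistics for every cell type
#' @export
setMethod("summarizeEnsemble", "SimEnsemble", function(x, ...) {
  types <- c("beta", "naive", "effector", "memory")
  blocks <- lapply(types, function(tp) {
    b <- quartileSummary(x, what = tp)
    b$cellType <- tp
    b
  })
  out <- do.call(rbind, blocks)
  out[, c("cellType", setdiff(names(out), "cellType"))]
})

#' Write ensemble summary files
#'
#' Writes `summary.csv` (per-day box statistics for all cell types) and
#' `metrics.json` (half-loss day, inflammation window, initial counts) for a
#' finished ensemble, mirroring the layout used by the scenario comparison
#' tables.
#'
#' @param ensemble a [SimEnsemble-class]
#' @param dir output directory (created if missing)
#' @return named list with the computed metrics, invisibly
#' @export
writeEnsembleSummary <- function(ensemble, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- summarizeEnsemble(ensemble)
  write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  hld <- halfLossDay(ensemble)
  win <- inflammationWindow(ensemble)
  med0 <- unname(.medianSeries(ensemble@runs, "beta")[1])
  metrics <- list(
    halfLossDay = if (is.na(hld)) NULL else hld,
    window = if (length(win) == 2 && !anyNA(win))
      list(onset = win[["onset"]], end = win[["end"]]) else NULL,
    medianInitialBeta = med0,
    nReplicates = length(ensemble@runs)
  )
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "metrics.json"))
  invisible(metrics)
}

#' Scenario comparison table
#'
#' Runs (or summarises) several scenario ensembles and lays out half-loss day
#' and inflammation window per scenario, reproducing the structure of the
#' published membrane-strength and T-cell-count comparisons.
#'
#' @param ensembles named list of [SimEnsemble-class] objects
#' @return data.frame with one row per scenario: membrane strength,
#'   regeneration rate, initial T cells, inflammation window and half-loss day
#' @export
scenarioTable <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  rows <- lapply(names(ensembles), function(nm) {
    ens <- ensembles[[nm]]
    cfg <- ens@config
    win <- inflammationWindow(ens)
    data.frame(
      scenario = nm,
      membraneStrength = cfg@membraneStrength,
      betaRegenRate = cfg@betaRegenRate,
      nInitialTcells = cfg@nInitialTcells,
      onsetDay = if (length(win) == 2) win[["onset"]] else NA_real_,
      endDay = if (length(win) == 2) win[["end"]] else NA_real_,
      halfLossDay = halfLossDay(ens)
    )
  })
  do.call(rbind, rows)
}
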