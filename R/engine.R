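# engine parameter list from a config
.engineParams <- function(config) {
  list(killProb = config@killProb,
       conjDuration = config@conjDuration,
       maxConjugates = config@maxConjugates,
       memoryDiffProb = config@memoryDiffProb,
       memoryDiffGeneration = config@memoryDiffGeneration,
       divisionCycleTime = config@divisionCycleTime,
       persMin = config@persistenceRange[1],
       persMax = config@persistenceRange[2],
       naiveLifespan = config@naiveLifespan,
       effectorLifespan = config@effectorLifespan,
       memoryLifespan = config@memoryLifespan,
       betaRegenRate = config@betaRegenRate,
       influxRate = config@influxRate,
       motility = config@motility)
}

# engine state list from tissue + cell records
.engineState <- function(tissue, cells, triggered = NULL) {
  if (is.null(triggered)) triggered <- integer(nIslets(tissue))
  cl <- as.list(cells)
  cl$subset <- match(cells$subset, .SUBSET_LEVELS) - 1L
  list(mem = tissue@membraneGrid,
       memIslet = tissue@membraneIslet,
       beta = tissue@betaGrid,
       interior = tissue@interiorGrid,
       triggered = as.integer(triggered),
       cells = cl)
}

# rebuild R-level tissue/cells from a dumped engine state
.fromEngineState <- function(state, tissue) {
  out <- tissue
  out@betaGrid <- state$beta
  out@membraneGrid <- state$mem
  out@areaFraction <- sum(state$beta > 0L) / (tissue@gridWidth * tissue@gridHeight)
  cells <- as.data.frame(state$cells)
  cells$subset <- .SUBSET_LEVELS[cells$subset + 1L]
  list(tissue = out, cells = cells, triggered = state$triggered != 0L)
}

.runToSeries <- function(raw) {
  s <- raw$series
  s$day <- s$tick / 1440
  s[, c("day", "beta", "naive", "effector", "memory", "kills", "divisions",
        "influx", "efflux", "deaths", "regenBirths", "openings")]
}

#' Run one simulation replicate
#'
#' Generates the tissue, places the initial T cells and advances the tick
#' loop for the configured horizon, recording a per-day census. The tick
#' applies, in fixed order: ageing and lifespan culling; conjugate countdown;
#' movement with boundary efflux; membrane degradation; memory recall;
#' conjugate formation and killing; activation and proliferation;
#' regeneration triggering and Beta division; influx. The same seed and
#' configuration give a bit-identical trajectory. A run that reaches total
#' extinction (no Beta cells and no T cells) is frozen and the remaining days
#' filled with the terminal counts.
#'
#' @param config a [SimConfig-class]
#' @param seed replicate seed
#' @param checkInvariants audit occupancy invariants during the run (slower;
#'   used in tests)
#' @param returnState also return the final tissue/cell state
#' @param stopAtBetaExtinction freeze the run once every Beta cell is gone
#'   (the Beta series is exactly zero from then on; the recorded T-cell
#'   counts are carried forward). Useful when only Beta-cell metrics are
#'   needed.
#' @return a [SimulationRun-class]
#' @examples
#' run <- runSimulation(simConfig(durationDays = 2), seed = 1)
#' head(series(run))
#' @export
runSimulation <- function(config, seed = config@seed,
                          checkInvariants = FALSE, returnState = FALSE,
                          stopAtBetaExtinction = FALSE) {
  set.seed(seed)
  tissue <- generateTissue(config)
  cells <- placeInitialTCells(config, tissue)
  state <- .engineState(tissue, cells)
  nTicks <- round(config@durationDays * 1440 / config@tickMinutes)
  raw <- .cpp_run(state, .engineParams(config), nTicks = nTicks,
                  recordEvery = 1440L, checkInvariants = checkInvariants,
                  returnState = returnState,
                  stopWhenBetaExtinct = stopAtBetaExtinction)
  run <- new("SimulationRun", series = .runToSeries(raw), events = raw$events,
             seed = as.integer(seed), initialBeta = raw$series$beta[1],
             earlyStopped = raw$earlyStopped)
  if (returnState) attr(run, "finalState") <- .fromEngineState(raw$state, tissue)
  run
}

#' Run a replicate ensemble
#'
#' Runs `nReplicates` independent replicates with seeds `baseSeed`,
#' `baseSeed + 1`, ... Each replicate generates its own tissue and inoculum.
#' Results can be persisted incrementally as `timeseries_<seed>.csv`.
#'
#' @param config a [SimConfig-class]
#' @param nReplicates ensemble size; defaults to the config value
#' @param baseSeed seed of the first replicate; defaults to the config value
#' @param outDir optional directory for incremental per-replicate CSVs
#' @param verbose print progress
#' @param stopAtBetaExtinction passed to [runSimulation()]
#' @return a [SimEnsemble-class]
#' @examples
#' ens <- runEnsemble(simConfig(durationDays = 1, nReplicates = 2), baseSeed = 1)
#' halfLossDay(ens)
#' @export
runEnsemble <- function(config, nReplicates = config@nReplicates,
                        baseSeed = config@seed, outDir = NULL,
                        verbose = FALSE, stopAtBetaExtinction = FALSE) {
  stopifnot(nReplicates >= 1)
  seeds <- baseSeed + seq_len(nReplicates) - 1L
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  runs <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    run <- runSimulation(config, seed = seeds[i],
                         stopAtBetaExtinction = stopAtBetaExtinction)
    runs[[i]] <- series(run)
    if (!is.null(outDir)) {
      f <- file.path(outDir, sprintf("timeseries_%d.csv", seeds[i]))
      write.csv(runs[[i]][, c("day", "beta", "naive", "effector", "memory")],
                f, row.names = FALSE)
    }
    if (verbose)
      message(sprintf("replicate %d/%d (seed %d) done", i, nReplicates, seeds[i]))
  }
  new("SimEnsemble", runs = runs, seeds = as.integer(seeds), config = config)
}

#' @describeIn runSimulation per-day time series of a run
#' @param x a [SimulationRun-class]
#' @export
setMethod("series", "SimulationRun", function(x) x@series)

#' @describeIn runSimulation total event counts of a run
#' @export
setMethod("eventCounts", "SimulationRun", function(x) x@events)

setMethod("show", "SimulationRun", function(object) {
  s <- object@series
  last <- s[nrow(s), ]
  cat(sprintf("SimulationRun (seed %d): %g days, Beta %g -> %g\n",
              object@seed, last$day, object@initialBeta, last$beta))
  cat(sprintf("  final T cells: %g naive, %g effector, %g memory%s\n",
              last$naive, last$effector, last$memory,
              if (object@earlyStopped) " (early stop)" else ""))
})

setMethod("show", "SimEnsemble", function(object) {
  cat(sprintf("SimEnsemble: %d replicates, seeds %d..%d\n",
              length(object@runs), min(object@seeds), max(object@seeds)))
  hld <- halfLossDay(object)
  cat(sprintf("  half-loss day: %s\n",
              if (is.na(hld)) "not reached" else format(hld)))
})

setMethod("length", "SimEnsemble", function(x) length(x@runs))
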