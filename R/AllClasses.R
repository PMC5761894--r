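#' @import methods
#' @importFrom stats median quantile rbinom rpois runif qbinom setNames
#' @importFrom utils write.csv read.csv
#' @useDynLib insulitisSim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# islet area fraction targets (% of tissue area) per density class
.DENSITY_RANGES <- list(
  low    = c(0.007, 0.031),
  medium = c(0.029, 0.052),
  high   = c(0.042, 0.077)
)

.SUBSET_LEVELS <- c("naive", "effector", "memory")

#' Simulation configuration
#'
#' Holds every tunable parameter of one insulitis scenario: tissue geometry,
#' basement-membrane strength, initial T-cell inoculum, motility, killing and
#' proliferation parameters, Beta-cell regeneration and the ensemble protocol.
#' Use [simConfig()] to construct and [scenarioPreset()] for the published
#' scenario presets.
#'
#' @slot gridWidth,gridHeight grid size in sites (default 200 x 200).
#' @slot siteSize site edge length in micrometres (10).
#' @slot tickMinutes time step in minutes (1).
#' @slot durationDays simulated horizon in days (70 = 10 weeks).
#' @slot membraneStrength basement-membrane strength in effector-minutes per
#'   ring site (range considered 1440--20160).
#' @slot isletDensityClass one of `"low"`, `"medium"`, `"high"`.
#' @slot densityRange optional explicit islet area-fraction range overriding
#'   the class range (fractions of tissue area; `NA` = use class range).
#' @slot isletDiameterRange islet diameter range in micrometres (100--160).
#' @slot nInitialTcells initial T-cell count (3--27).
#' @slot effectorToNaive effector:naive ratio of the inoculum (2 means 2:1).
#' @slot betaRegenRate Beta-cell regeneration rate, fraction per day (0--0.05).
#' @slot killProb kill probability at conjugate formation (0.55).
#' @slot conjDuration conjugate lifetime in minutes (90).
#' @slot maxConjugates simultaneous conjugates per effector (2).
#' @slot memoryDiffProb memory differentiation probability per division
#'   product (0.2).
#' @slot memoryDiffGeneration first generation eligible for memory
#'   differentiation (8).
#' @slot naiveLifespan,effectorLifespan,memoryLifespan lifespans in minutes
#'   (8 weeks, 6 days, 6 months).
#' @slot tcellSpeed movement speed in micrometres per minute (10).
#' @slot persistenceRange persistence time range in minutes (1--4).
#' @slot influxRate daily T-cell influx as a fraction of the resident
#'   population (0.017).
#' @slot divisionCycleTime fast cell-cycle duration in minutes (1440).
#' @slot nReplicates ensemble size (100).
#' @slot seed base random seed.
#' @slot motility logical; `FALSE` freezes all movement (micro-fixtures only).
#' @exportClass SimConfig
setClass("SimConfig", representation(
  gridWidth = "integer", gridHeight = "integer",
  siteSize = "numeric", tickMinutes = "numeric", durationDays = "numeric",
  membraneStrength = "numeric",
  isletDensityClass = "character", densityRange = "numeric",
  isletDiameterRange = "numeric",
  nInitialTcells = "integer", effectorToNaive = "numeric",
  betaRegenRate = "numeric",
  killProb = "numeric", conjDuration = "integer", maxConjugates = "integer",
  memoryDiffProb = "numeric", memoryDiffGeneration = "integer",
  naiveLifespan = "numeric", effectorLifespan = "numeric",
  memoryLifespan = "numeric",
  tcellSpeed = "numeric", persistenceRange = "integer",
  influxRate = "numeric", divisionCycleTime = "integer",
  nReplicates = "integer", seed = "integer", motility = "logical"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chkProb <- function(p, nm) {
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
      msg <<- c(msg, sprintf("%s must be a probability in [0, 1]", nm))
  }
  chkPos <- function(v, nm) {
    if (length(v) != 1 || is.na(v) || v <= 0)
      msg <<- c(msg, sprintf("%s must be a positive scalar", nm))
  }
  chkProb(object@killProb, "killProb")
  chkProb(object@memoryDiffProb, "memoryDiffProb")
  chkProb(object@influxRate, "influxRate")
  if (object@betaRegenRate < 0)
    msg <- c(msg, "betaRegenRate must be non-negative")
  chkPos(object@siteSize, "siteSize")
  chkPos(object@tickMinutes, "tickMinutes")
  chkPos(object@membraneStrength, "membraneStrength")
  chkPos(object@naiveLifespan, "naiveLifespan")
  chkPos(object@effectorLifespan, "effectorLifespan")
  chkPos(object@memoryLifespan, "memoryLifespan")
  chkPos(object@conjDuration, "conjDuration")
  chkPos(object@divisionCycleTime, "divisionCycleTime")
  if (object@durationDays < 0) msg <- c(msg, "durationDays must be >= 0")
  if (object@gridWidth < 1 || object@gridHeight < 1)
    msg <- c(msg, "grid must have positive dimensions")
  if (!object@isletDensityClass %in% names(.DENSITY_RANGES))
    msg <- c(msg, "isletDensityClass must be one of 'low', 'medium', 'high'")
  if (length(object@isletDiameterRange) != 2 ||
      any(object@isletDiameterRange <= 0) ||
      diff(object@isletDiameterRange) < 0)
    msg <- c(msg, "isletDiameterRange must be an increasing positive pair")
  maxDiam <- max(object@isletDiameterRange) / object@siteSize
  if (maxDiam + 4 > min(object@gridWidth, object@gridHeight))
    msg <- c(msg, "islet diameter range does not fit inside the grid")
  if (length(object@densityRange) == 2 && !anyNA(object@densityRange)) {
    if (any(object@densityRange < 0) || diff(object@densityRange) < 0 ||
        max(object@densityRange) >= 1)
      msg <- c(msg, "densityRange must be an increasing pair of fractions")
  }
  if (object@nInitialTcells < 0)
    msg <- c(msg, "nInitialTcells must be non-negative")
  if (object@effectorToNaive < 0)
    msg <- c(msg, "effectorToNaive must be non-negative")
  if (object@maxConjugates < 0)
    msg <- c(msg, "maxConjugates must be non-negative")
  if (object@memoryDiffGeneration < 1)
    msg <- c(msg, "memoryDiffGeneration must be >= 1")
  if (length(object@persistenceRange) != 2 ||
      any(object@persistenceRange < 1) ||
      diff(object@persistenceRange) < 0)
    msg <- c(msg, "persistenceRange must be an increasing pair of minutes >= 1")
  if (abs(object@tcellSpeed * object@tickMinutes - object@siteSize) > 1e-9)
    msg <- c(msg, "tcellSpeed x tickMinutes must equal siteSize (1 site per tick)")
  if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic pancreatic tissue section
#'
#' The generated islet layout: Beta-cell occupancy, the per-site basement
#' membrane strength map (one-site-thick perimeter rings), the original islet
#' footprint, and per-islet bookkeeping. Produced by [generateTissue()].
#'
#' @slot gridWidth,gridHeight grid size in sites.
#' @slot islets data.frame with one row per islet: `id`, `cx`, `cy` (centre,
#'   1-based site coordinates), `radius` (sites), `nBeta` (initial Beta count).
#' @slot betaGrid integer matrix `[x, y]`; islet id of the Beta cell occupying
#'   a site, 0 if empty.
#' @slot membraneGrid numeric matrix; remaining membrane strength in minutes,
#'   `NA` outside membrane rings.
#' @slot membraneIslet integer matrix; islet id of each ring site.
#' @slot interiorGrid integer matrix; original islet footprint id.
#' @slot areaFraction achieved islet area fraction of the tissue.
#' @slot membraneStrength initial strength the rings were set to.
#' @exportClass Tissue
setClass("Tissue", representation(
  gridWidth = "integer", gridHeight = "integer",
  islets = "data.frame",
  betaGrid = "matrix", membraneGrid = "matrix",
  membraneIslet = "matrix", interiorGrid = "matrix",
  areaFraction = "numeric", membraneStrength = "numeric"
))

setValidity("Tissue", function(object) {
  msg <- character()
  dims <- c(object@gridWidth, object@gridHeight)
  for (nm in c("betaGrid", "membraneGrid", "membraneIslet", "interiorGrid")) {
    if (!identical(dim(slot(object, nm)), as.integer(dims)))
      msg <- c(msg, sprintf("%s has wrong dimensions", nm))
  }
  m <- object@membraneGrid
  if (any(m[!is.na(m)] < 0)) msg <- c(msg, "membrane values must be >= 0")
  if (any(!is.na(m) & object@membraneIslet == 0))
    msg <- c(msg, "membrane values outside membrane sites")
  nBeta <- sum(object@betaGrid > 0)
  frac <- nBeta / prod(dims)
  if (nrow(object@islets) > 0 && abs(frac - object@areaFraction) > 1 / prod(dims))
    msg <- c(msg, "areaFraction does not match Beta occupancy")
  if (length(msg)) msg else TRUE
})

#' One simulation replicate
#'
#' @slot series data.frame of per-day records: `day`, `beta`, `naive`,
#'   `effector`, `memory` plus cumulative event counters (`kills`,
#'   `divisions`, `influx`, `efflux`, `deaths`, `regenBirths`, `openings`).
#' @slot events named numeric of total event counts.
#' @slot seed the replicate seed.
#' @slot initialBeta Beta count at day 0.
#' @slot earlyStopped whether the run froze after total extinction.
#' @exportClass SimulationRun
setClass("SimulationRun", representation(
  series = "data.frame", events = "numeric", seed = "integer",
  initialBeta = "numeric", earlyStopped = "logical"
))

#' A replicate ensemble of one scenario
#'
#' @slot runs list of per-day `series` data.frames, one per replicate.
#' @slot seeds integer vector of replicate seeds.
#' @slot config the shared [SimConfig-class] of the scenario.
#' @exportClass SimEnsemble
setClass("SimEnsemble", representation(
  runs = "list", seeds = "integer", config = "SimConfig"
))

setValidity("SimEnsemble", function(object) {
  if (length(object@runs) != length(object@seeds))
    return("one seed per replicate required")
  TRUE
})
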