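#' Create a simulation configuration
#'
#' Constructs a [SimConfig-class] with the model's default parameterisation: a
#' 200 x 200 grid of 10 um sites, 1-minute ticks, a 10-week horizon, medium
#' islet density, membrane strength 20160 effector-minutes per site, three
#' initial T cells at a 2:1 effector:naive ratio, 55% kill probability on
#' 90-minute conjugates (at most two per effector), memory differentiation at
#' 20% from generation 8, literature lifespans (naive 8 weeks, effector
#' 6 days, memory 6 months), 10 um/min motility with 1--4 min persistence,
#' 1.7%/day influx and 5%/day Beta regeneration.
#'
#' @param gridWidth,gridHeight grid size in sites.
#' @param siteSize site edge length (um).
#' @param tickMinutes tick length (minutes).
#' @param durationDays simulated days.
#' @param membraneStrength effector-minutes needed to open one membrane site.
#' @param isletDensityClass `"low"`, `"medium"` or `"high"`.
#' @param densityRange explicit area-fraction range (fractions), or `NA` to
#'   use the class range. `c(0, 0)` yields an empty tissue.
#' @param isletDiameterRange islet diameter range (um).
#' @param nInitialTcells initial T-cell count.
#' @param effectorToNaive effector:naive ratio (2 = "2:1").
#' @param betaRegenRate Beta regeneration rate, fraction per day.
#' @param killProb kill probability at conjugate formation.
#' @param conjDuration conjugate lifetime (minutes).
#' @param maxConjugates simultaneous conjugates per effector.
#' @param memoryDiffProb memory differentiation probability.
#' @param memoryDiffGeneration first memory-eligible generation.
#' @param naiveLifespan,effectorLifespan,memoryLifespan lifespans (minutes).
#' @param tcellSpeed movement speed (um/min); must equal one site per tick.
#' @param persistenceRange persistence time range (whole minutes).
#' @param influxRate daily influx fraction of the resident population.
#' @param divisionCycleTime fast cell-cycle duration (minutes).
#' @param nReplicates ensemble size.
#' @param seed base random seed.
#' @param motility `FALSE` freezes movement; micro-fixtures only.
#' @return a validated [SimConfig-class]
#' @examples
#' cfg <- simConfig(nInitialTcells = 9L, membraneStrength = 10080)
#' effectorNaiveSplit(cfg)
#' @export
simConfig <- function(gridWidth = 200L, gridHeight = 200L,
                      siteSize = 10, tickMinutes = 1, durationDays = 70,
                      membraneStrength = 20160,
                      isletDensityClass = "medium",
                      densityRange = c(NA_real_, NA_real_),
                      isletDiameterRange = c(100, 160),
                      nInitialTcells = 3L, effectorToNaive = 2,
                      betaRegenRate = 0.05,
                      killProb = 0.55, conjDuration = 90L, maxConjugates = 2L,
                      memoryDiffProb = 0.2, memoryDiffGeneration = 8L,
                      naiveLifespan = 8 * 7 * 1440,
                      effectorLifespan = 6 * 1440,
                      memoryLifespan = 262800,
                      tcellSpeed = 10, persistenceRange = c(1L, 4L),
                      influxRate = 0.017, divisionCycleTime = 360L,
                      nReplicates = 100L, seed = 1L, motility = TRUE) {
  new("SimConfig",
      gridWidth = as.integer(gridWidth), gridHeight = as.integer(gridHeight),
      siteSize = siteSize, tickMinutes = tickMinutes,
      durationDays = durationDays, membraneStrength = membraneStrength,
      isletDensityClass = isletDensityClass,
      densityRange = as.numeric(densityRange),
      isletDiameterRange = as.numeric(isletDiameterRange),
      nInitialTcells = as.integer(nInitialTcells),
      effectorToNaive = effectorToNaive, betaRegenRate = betaRegenRate,
      killProb = killProb, conjDuration = as.integer(conjDuration),
      maxConjugates = as.integer(maxConjugates),
      memoryDiffProb = memoryDiffProb,
      memoryDiffGeneration = as.integer(memoryDiffGeneration),
      naiveLifespan = naiveLifespan, effectorLifespan = effectorLifespan,
      memoryLifespan = memoryLifespan,
      tcellSpeed = tcellSpeed,
      persistenceRange = as.integer(persistenceRange),
      influxRate = influxRate,
      divisionCycleTime = as.integer(divisionCycleTime),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed),
      motility = motility)
}

#' Effector/naive split of the initial inoculum
#'
#' The effector count is `round(n * r / (r + 1))` for ratio `r`:1, the naive
#' count the remainder, reproducing 2:1 exactly for n in 3, 9, 27.
#'
#' @param config a [SimConfig-class]
#' @return named integer vector `c(effector, naive)`
#' @export
effectorNaiveSplit <- function(config) {
  n <- config@nInitialTcells
  r <- config@effectorToNaive
  eff <- as.integer(round(n * r / (r + 1)))
  c(effector = eff, naive = n - eff)
}

#' Published scenario presets
#'
#' Named configurations for the basement-membrane-strength comparison
#' (strengths 20160, 10080 and 1440, each with regeneration at 5\%/day or
#' disabled) and the initial T-cell-count comparison (9 and 27 cells at
#' strength 20160 with 5\%/day regeneration). All use medium islet density
#' and a 2:1 effector:naive inoculum.
#'
#' @param name one of `"table2-bm20160-regen"`, `"table2-bm20160-noregen"`,
#'   `"table2-bm10080-regen"`, `"table2-bm10080-noregen"`,
#'   `"table2-bm1440-regen"`, `"table2-bm1440-noregen"`, `"table3-t9"`,
#'   `"table3-t27"`.
#' @param ... overrides passed to [simConfig()] (e.g. `seed`,
#'   `durationDays`, `nReplicates`).
#' @return a [SimConfig-class]
#' @examples
#' scenarioPreset("table2-bm1440-regen", durationDays = 20)
#' @export
scenarioPreset <- function(name, ...) {
  presets <- list(
    "table2-bm20160-regen"   = list(membraneStrength = 20160, betaRegenRate = 0.05),
    "table2-bm20160-noregen" = list(membraneStrength = 20160, betaRegenRate = 0),
    "table2-bm10080-regen"   = list(membraneStrength = 10080, betaRegenRate = 0.05),
    "table2-bm10080-noregen" = list(membraneStrength = 10080, betaRegenRate = 0),
    "table2-bm1440-regen"    = list(membraneStrength = 1440,  betaRegenRate = 0.05),
    "table2-bm1440-noregen"  = list(membraneStrength = 1440,  betaRegenRate = 0),
    "table3-t9"  = list(membraneStrength = 20160, betaRegenRate = 0.05,
                        nInitialTcells = 9L),
    "table3-t27" = list(membraneStrength = 20160, betaRegenRate = 0.05,
                        nInitialTcells = 27L)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  args <- presets[[name]]
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

#' List available scenario presets
#' @return character vector of preset names
#' @export
scenarioPresets <- function() {
  c("table2-bm20160-regen", "table2-bm20160-noregen",
    "table2-bm10080-regen", "table2-bm10080-noregen",
    "table2-bm1440-regen", "table2-bm1440-noregen",
    "table3-t9", "table3-t27")
}

#' Read a configuration from a flat key-value text file
#'
#' Lines of the form `key = value` (or `key: value`) with the field names of
#' [simConfig()]; `#` starts a comment. Two-element fields (ranges) are given
#' comma-separated. Unknown keys are an error.
#'
#' @param path file path
#' @param ... overrides applied after reading (e.g. from CLI flags)
#' @return a [SimConfig-class]
#' @export
readSimConfig <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(formals(simConfig)))
      stop("unknown configuration key: ", key)
    parts <- trimws(strsplit(val, ",")[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (anyNA(parsed)) {
      low <- tolower(parts)
      if (all(low %in% c("true", "false"))) parsed <- low == "true"
      else parsed <- parts
    }
    args[[key]] <- parsed
  }
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

#' Write a configuration as a flat key-value text file
#' @param config a [SimConfig-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeSimConfig <- function(config, path) {
  nms <- names(formals(simConfig))
  lines <- vapply(nms, function(nm) {
    v <- slot(config, nm)
    paste0(nm, " = ", paste(v, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

setMethod("show", "SimConfig", function(object) {
  rng <- object@densityRange
  dens <- if (length(rng) == 2 && !anyNA(rng))
    sprintf("[%.3f, %.3f] (override)", rng[1], rng[2])
  else object@isletDensityClass
  split <- effectorNaiveSplit(object)
  cat("SimConfig\n",
      sprintf("  grid: %d x %d sites (%.0f um), tick %.0f min, %g days\n",
              object@gridWidth, object@gridHeight, object@siteSize,
              object@tickMinutes, object@durationDays),
      sprintf("  membrane strength: %g min/site; islet density: %s; diameter %g-%g um\n",
              object@membraneStrength, dens,
              object@isletDiameterRange[1], object@isletDiameterRange[2]),
      sprintf("  T cells: %d (%d effector : %d naive); regen %g%%/day; kill p = %g\n",
              object@nInitialTcells, split[["effector"]], split[["naive"]],
              100 * object@betaRegenRate, object@killProb),
      sprintf("  replicates: %d, base seed: %d\n",
              object@nReplicates, object@seed), sep = "")
})
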