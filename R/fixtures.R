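# build a Tissue from explicit site lists (fixtures and tests)
.syntheticTissue <- function(W, H, betaSites = NULL, interiorSites = NULL,
                             membraneSites = NULL, strength = 1440,
                             islets = NULL) {
  betaGrid <- matrix(0L, W, H)
  interiorGrid <- matrix(0L, W, H)
  membraneGrid <- matrix(NA_real_, W, H)
  membraneIslet <- matrix(0L, W, H)
  if (!is.null(betaSites) && nrow(betaSites))
    betaGrid[cbind(betaSites$x, betaSites$y)] <- as.integer(betaSites$id)
  if (!is.null(interiorSites) && nrow(interiorSites))
    interiorGrid[cbind(interiorSites$x, interiorSites$y)] <-
      as.integer(interiorSites$id)
  if (!is.null(membraneSites) && nrow(membraneSites)) {
    s <- if (!is.null(membraneSites$strength)) membraneSites$strength
         else rep(strength, nrow(membraneSites))
    membraneGrid[cbind(membraneSites$x, membraneSites$y)] <- s
    membraneIslet[cbind(membraneSites$x, membraneSites$y)] <-
      as.integer(membraneSites$id)
  }
  if (is.null(islets)) {
    ids <- sort(unique(c(betaGrid[betaGrid > 0], membraneIslet[membraneIslet > 0])))
    islets <- data.frame(id = as.integer(ids),
                         cx = rep(NA_integer_, length(ids)),
                         cy = rep(NA_integer_, length(ids)),
                         radius = rep(NA_real_, length(ids)),
                         nBeta = vapply(ids, function(i) sum(betaGrid == i),
                                        integer(1)))
  }
  new("Tissue", gridWidth = as.integer(W), gridHeight = as.integer(H),
      islets = islets, betaGrid = betaGrid, membraneGrid = membraneGrid,
      membraneIslet = membraneIslet, interiorGrid = interiorGrid,
      areaFraction = sum(betaGrid > 0) / (W * H),
      membraneStrength = strength)
}

# a full islet (disk + ring) at an explicit centre, for fixtures
.fixtureIslet <- function(cx, cy, r, id = 1L) {
  disk <- .diskOffsets(r)
  ring <- .ringOffsets(disk)
  list(beta = data.frame(x = cx + disk$dx, y = cy + disk$dy, id = id),
       ring = data.frame(x = cx + ring$dx, y = cy + ring$dy, id = id))
}

#' Deterministic micro-fixtures
#'
#' Small, fully specified tissue/agent setups that make single rules testable
#' without full-scale runs. Every stochastic rule has a fixture whose
#' deterministic limit (probability 0 or 1, frozen motility) is checked
#' exactly, plus statistical fixtures at the literature parameter values.
#'
#' Available fixtures:
#' \describe{
#'   \item{`lone_effector_breach`}{one effector frozen beside a single
#'     membrane site of strength `S`: the opening forms at exactly tick `S`.}
#'   \item{`certain_kill`}{kill probability 1, effector adjacent to one
#'     exposed Beta cell: the Beta cell dies on tick 1.}
#'   \item{`branching_lineage`}{one naive cell meets one Beta cell on an
#'     otherwise empty grid (no killing, no deaths): the single encounter
#'     commits the lineage to the programmed burst, which doubles every
#'     division cycle -- `2^g` cells after `g` cycles.}
#'   \item{`quiet_tissue`}{two walled islets and no T cells: every count and
#'     membrane value stays constant.}
#'   \item{`regrowth_only`}{isolated pre-triggered single-cell islets with no
#'     attackers: growth follows the branching-process mean
#'     `(1 + rate/1440)^ticks`.}
#'   \item{`kill_statistics`}{a grid of isolated effector/Beta pairs; each
#'     pair yields one independent kill draw at `killProb`.}
#'   \item{`memory_statistics`}{a grid of isolated generation-7 naive/Beta
#'     pairs with a short cycle; each division yields two independent memory
#'     draws at `memoryDiffProb`.}
#' }
#'
#' @param name fixture name (see above)
#' @param strength membrane strength for `lone_effector_breach`
#' @param pairs grid of pairs per side for the statistical fixtures
#' @param size grid half-width for `branching_lineage`
#' @return list with elements `name`, `tissue`, `cells`, `config`,
#'   `triggered` and `note` (the expected behaviour, as text)
#' @examples
#' fx <- buildFixture("certain_kill")
#' res <- runFixture(fx, ticks = 1)
#' res$series$beta   # 1, then 0
#' @export
buildFixture <- function(name, strength = 1440, pairs = 50L, size = 400L) {
  base <- simConfig(nReplicates = 1L)
  fx <- switch(
    name,
    lone_effector_breach = {
      tissue <- .syntheticTissue(
        11, 11, membraneSites = data.frame(x = 6, y = 6, id = 1),
        strength = strength)
      list(tissue = tissue,
           cells = newTCells(7, 6, subset = "effector"),
           config = simConfig(motility = FALSE, influxRate = 0,
                              membraneStrength = strength,
                              naiveLifespan = 1e9, effectorLifespan = 1e9,
                              memoryLifespan = 1e9, nReplicates = 1L),
           note = sprintf("single membrane site opens at exactly tick %g",
                          strength))
    },
    certain_kill = {
      tissue <- .syntheticTissue(
        11, 11, betaSites = data.frame(x = 6, y = 6, id = 1))
      list(tissue = tissue,
           cells = newTCells(7, 6, subset = "effector"),
           config = simConfig(killProb = 1, motility = FALSE, influxRate = 0,
                              betaRegenRate = 0, nReplicates = 1L),
           note = "exposed Beta cell dies on the tick of first contact")
    },
    branching_lineage = {
      # one naive cell meets one Beta cell on an otherwise empty grid wide
      # enough that descendants neither crowd each other nor reach the edge;
      # the single encounter commits the lineage to the programmed burst
      W <- 2L * size + 1L
      mid <- size + 1L
      tissue <- .syntheticTissue(W, W,
                                 betaSites = data.frame(x = mid, y = mid, id = 1))
      # the founder walks into the Beta cell (blocked step) so the first
      # encounter is guaranteed on tick one
      list(tissue = tissue,
           cells = newTCells(mid + 1L, mid, subset = "naive",
                             direction = 4L, persistence = 10L),
           config = simConfig(influxRate = 0, betaRegenRate = 0,
                              killProb = 0, maxConjugates = 0L,
                              divisionCycleTime = 360L,
                              naiveLifespan = 1e9, effectorLifespan = 1e9,
                              memoryLifespan = 1e9, nReplicates = 1L),
           note = "lineage doubles each cycle: 2^g cells after g cycles")
    },
    quiet_tissue = {
      i1 <- .fixtureIslet(25, 25, 5, 1L)
      i2 <- .fixtureIslet(70, 60, 7, 2L)
      tissue <- .syntheticTissue(
        100, 100,
        betaSites = rbind(i1$beta, i2$beta),
        interiorSites = rbind(i1$beta, i2$beta),
        membraneSites = rbind(i1$ring, i2$ring),
        strength = strength)
      list(tissue = tissue, cells = newTCells(integer(), integer()),
           config = simConfig(membraneStrength = strength, nReplicates = 1L),
           note = "no attackers: all counts and membrane values constant")
    },
    regrowth_only = {
      xs <- seq(3, 98, by = 5)
      g <- expand.grid(x = xs, y = xs)
      g$id <- seq_len(nrow(g))
      tissue <- .syntheticTissue(100, 100, betaSites = g, interiorSites = g)
      list(tissue = tissue, cells = newTCells(integer(), integer()),
           config = simConfig(betaRegenRate = 0.05, nReplicates = 1L),
           triggered = rep(TRUE, nrow(g)),
           note = "pre-triggered islets grow at the branching-process mean")
    },
    kill_statistics = {
      xs <- 4 * seq_len(pairs) - 2
      g <- expand.grid(x = xs, y = xs)
      g$id <- seq_len(nrow(g))
      tissue <- .syntheticTissue(4 * pairs + 2, 4 * pairs + 2, betaSites = g)
      cells <- newTCells(g$x + 1L, g$y, subset = "effector")
      list(tissue = tissue, cells = cells,
           config = simConfig(motility = FALSE, influxRate = 0,
                              betaRegenRate = 0, divisionCycleTime = 10000L,
                              nReplicates = 1L),
           note = "one independent kill draw per isolated pair")
    },
    memory_statistics = {
      xs <- 4 * seq_len(pairs) - 2
      g <- expand.grid(x = xs, y = xs)
      g$id <- seq_len(nrow(g))
      tissue <- .syntheticTissue(4 * pairs + 2, 4 * pairs + 2, betaSites = g)
      cells <- newTCells(g$x + 1L, g$y, subset = "naive", generation = 7L)
      list(tissue = tissue, cells = cells,
           config = simConfig(motility = FALSE, influxRate = 0,
                              betaRegenRate = 0, maxConjugates = 0L,
                              divisionCycleTime = 5L,
                              naiveLifespan = 1e9, effectorLifespan = 1e9,
                              memoryLifespan = 1e9, nReplicates = 1L),
           note = "two generation-8 products (memory draws) per pair")
    },
    stop("unknown fixture '", name, "'; see ?buildFixture")
  )
  fx$name <- name
  if (is.null(fx$triggered)) fx$triggered <- logical(nIslets(fx$tissue))
  fx
}

#' Run a micro-fixture through the engine
#'
#' @param fixture a fixture from [buildFixture()]
#' @param ticks number of one-minute ticks to advance
#' @param recordEvery recording interval in ticks
#' @param returnState return the final tissue/cell state as well
#' @return list: `series` (per-record counts and cumulative event counters),
#'   `events` (totals), and optionally `state`
#' @export
runFixture <- function(fixture, ticks, recordEvery = 1L, returnState = TRUE) {
  state <- .engineState(fixture$tissue, fixture$cells,
                        triggered = fixture$triggered)
  raw <- .cpp_run(state, .engineParams(fixture$config), nTicks = as.integer(ticks),
                  recordEvery = as.integer(recordEvery),
                  checkInvariants = TRUE, returnState = returnState,
                  earlyStop = FALSE)
  out <- list(series = raw$series, events = raw$events)
  if (returnState)
    out$state <- .fromEngineState(raw$state, fixture$tissue)
  out
}

#' Exact binomial acceptance check
#'
#' Passes when the observed success count lies inside the central exact
#' `1 - alpha` binomial acceptance region for success probability `p`: the
#' region between the `alpha/2` and `1 - alpha/2` quantiles of
#' `Binomial(n, p)`. Used for the 55\% kill and 20\% memory-differentiation
#' checks.
#'
#' @param successes observed success count
#' @param n number of Bernoulli trials (at least 100)
#' @param p nominal success probability
#' @param alpha significance level (default 0.01)
#' @return `TRUE`/`FALSE`, with the acceptance region attached as attribute
#'   `region`
#' @examples
#' statisticalCheck(5500, 10000, 0.55)   # TRUE
#' statisticalCheck(5000, 10000, 0.55)   # FALSE
#' @export
statisticalCheck <- function(successes, n, p, alpha = 0.01) {
  if (n < 100) stop("statisticalCheck needs at least 100 trials")
  lo <- qbinom(alpha / 2, n, p)
  hi <- qbinom(1 - alpha / 2, n, p)
  out <- successes >= lo && successes <= hi
  attr(out, "region") <- c(lower = lo, upper = hi)
  out
}
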