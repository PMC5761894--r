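# the 8 lattice directions, same order as the engine
.DX <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.DY <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

.lifespans <- function(config) {
  c(naive = config@naiveLifespan,
    effector = config@effectorLifespan,
    memory = config@memoryLifespan)
}

# is any Beta cell in the Moore neighbourhood of (x, y)?
.betaAdjacent <- function(tissue, x, y) {
  W <- tissue@gridWidth; H <- tissue@gridHeight
  nx <- x + .DX; ny <- y + .DY
  ok <- nx >= 1 & nx <= W & ny >= 1 & ny <= H
  any(tissue@betaGrid[cbind(nx[ok], ny[ok])] > 0L)
}

# antigen contact: an adjacent Beta cell that is physically accessible (not
# separated by intact basement membrane); one predicate for activation,
# cycling, recall and conjugation
.antigenContact <- function(tissue, x, y) {
  W <- tissue@gridWidth; H <- tissue@gridHeight
  nx <- x + .DX; ny <- y + .DY
  ok <- which(nx >= 1 & nx <= W & ny >= 1 & ny <= H)
  for (d in ok) {
    if (tissue@betaGrid[nx[d], ny[d]] > 0L &&
        .conjugable(tissue, c(x, y), c(nx[d], ny[d]))) return(TRUE)
  }
  FALSE
}

# effector engagement with intact membrane in the Moore neighbourhood
# (own site included): engaged effectors arrest and erode the ring
.membraneEngaged <- function(tissue, x, y) {
  xs <- max(1, x - 1):min(tissue@gridWidth, x + 1)
  ys <- max(1, y - 1):min(tissue@gridHeight, y + 1)
  m <- tissue@membraneGrid[xs, ys]
  any(!is.na(m) & m > 0)
}

# an opened ring site in the Moore neighbourhood (own site included)
.openingAdjacent <- function(tissue, x, y) {
  xs <- max(1, x - 1):min(tissue@gridWidth, x + 1)
  ys <- max(1, y - 1):min(tissue@gridHeight, y + 1)
  m <- tissue@membraneGrid[xs, ys]
  any(!is.na(m) & m <= 0)
}

# occupancy matrix (cell row index, 0 = free) from cell records
.occupancy <- function(tissue, cells) {
  occ <- matrix(0L, tissue@gridWidth, tissue@gridHeight)
  if (nrow(cells)) {
    if (anyDuplicated(cells[, c("x", "y")]))
      stop("two T cells share a site")
    occ[cbind(cells$x, cells$y)] <- seq_len(nrow(cells))
  }
  occ
}

# may a cell standing at `from` (x, y pair) occupy `to`? Intact membrane
# blocks crossings between ring and islet interior, not transit over the ring
.canOccupy <- function(tissue, occ, from, to) {
  if (occ[to[1], to[2]] != 0L) return(FALSE)
  if (tissue@betaGrid[to[1], to[2]] != 0L) return(FALSE)
  fromIn <- tissue@interiorGrid[from[1], from[2]] > 0L
  toIn <- tissue@interiorGrid[to[1], to[2]] > 0L
  fromMem <- tissue@membraneGrid[from[1], from[2]]
  toMem <- tissue@membraneGrid[to[1], to[2]]
  if (!fromIn && toIn) {
    if (is.na(fromMem)) return(FALSE)           # interior only entered via ring
    if (fromMem > 0) return(FALSE)
  }
  if (fromIn && !toIn && !is.na(toMem) && toMem > 0) return(FALSE)
  TRUE
}

#' Remove T cells that reached their lifespan
#'
#' Removes every cell whose age is at or above its subset lifespan (naive
#' 8 weeks, effector 6 days, memory 6 months by default); all other cells are
#' returned unchanged.
#'
#' @param cells T-cell records (see [newTCells()])
#' @param config a [SimConfig-class]
#' @return the surviving cell records
#' @examples
#' cells <- newTCells(1:2, 1, subset = "effector", age = c(0, 6 * 1440))
#' cullExpired(cells, simConfig())   # the aged effector is removed
#' @export
cullExpired <- function(cells, config) {
  ls <- .lifespans(config)
  cells[cells$age < ls[cells$subset], , drop = FALSE]
}

#' Memory recall on antigen contact
#'
#' Memory cells with a Beta cell in their Moore neighbourhood re-acquire
#' effector function: the subset becomes effector and the age clock restarts
#' at 0 (the effector lifespan starts counting). Generation and position are
#' preserved.
#'
#' @param cells memory T-cell records; an error is raised if any row is not a
#'   memory cell
#' @param tissue a [Tissue-class]
#' @return the updated records
#' @export
memoryRecall <- function(cells, tissue) {
  if (any(cells$subset != "memory"))
    stop("memoryRecall invoked on non-memory cells")
  contact <- vapply(seq_len(nrow(cells)), function(i)
    .antigenContact(tissue, cells$x[i], cells$y[i]), logical(1))
  cells$subset[contact] <- "effector"
  cells$age[contact] <- 0
  cells
}

#' One tick of persistent random-walk movement with boundary efflux
#'
#' Cells move one site per minute in a persistent random walk: when the
#' persistence counter reaches zero a new direction is drawn uniformly from
#' the 8 lattice directions and a new persistence time uniformly from the
#' configured range. Steps onto occupied sites are blocked (the tick is
#' wasted); steps across the grid edge remove the cell (efflux to
#' neighbouring tissue). Conjugated cells and cycling cells in Beta contact
#' do not move. Cells are processed in a randomised order.
#'
#' @param cells T-cell records
#' @param tissue a [Tissue-class]
#' @param config a [SimConfig-class]
#' @return list with elements `cells` (survivors, updated) and `efflux`
#'   (number of cells that left the tissue)
#' @export
stepCells <- function(cells, tissue, config) {
  occ <- .occupancy(tissue, cells)
  W <- tissue@gridWidth; H <- tissue@gridHeight
  pmin_ <- config@persistenceRange[1]; pmax_ <- config@persistenceRange[2]
  gone <- logical(nrow(cells))
  for (i in sample.int(nrow(cells))) {
    if (cells$conj1[i] > 0 || cells$conj2[i] > 0) next
    if (cells$cycling[i] && .antigenContact(tissue, cells$x[i], cells$y[i])) next
    if (cells$subset[i] == "effector" &&
        .membraneEngaged(tissue, cells$x[i], cells$y[i]) &&
        !.openingAdjacent(tissue, cells$x[i], cells$y[i]) &&
        !.antigenContact(tissue, cells$x[i], cells$y[i])) next
    # invasion through a reachable breach takes precedence over the walk
    if (tissue@interiorGrid[cells$x[i], cells$y[i]] == 0L) {
      nx <- cells$x[i] + .DX; ny <- cells$y[i] + .DY
      ok <- which(nx >= 1 & nx <= W & ny >= 1 & ny <= H)
      canGo <- function(d) .canOccupy(tissue, occ, c(cells$x[i], cells$y[i]),
                                      c(nx[d], ny[d]))
      inv <- ok[tissue@interiorGrid[cbind(nx[ok], ny[ok])] > 0L]
      inv <- inv[vapply(inv, canGo, logical(1))]
      if (length(inv) == 0 &&
          tissue@membraneIslet[cells$x[i], cells$y[i]] == 0L) {
        m <- tissue@membraneGrid[cbind(nx[ok], ny[ok])]
        inv <- ok[!is.na(m) & m <= 0]
        inv <- inv[vapply(inv, canGo, logical(1))]
      }
      if (length(inv) > 0) {
        d <- inv[sample.int(length(inv), 1)]
        occ[cells$x[i], cells$y[i]] <- 0L
        occ[nx[d], ny[d]] <- i
        cells$x[i] <- nx[d]; cells$y[i] <- ny[d]
        next
      }
    }
    if (cells$persistence[i] <= 0) {
      cells$direction[i] <- sample.int(8L, 1) - 1L
      cells$persistence[i] <- sample(pmin_:pmax_, 1)
    }
    d <- cells$direction[i] + 1L
    nx <- cells$x[i] + .DX[d]; ny <- cells$y[i] + .DY[d]
    if (nx < 1 || nx > W || ny < 1 || ny > H) {
      occ[cells$x[i], cells$y[i]] <- 0L
      gone[i] <- TRUE
      next
    }
    if (.canOccupy(tissue, occ, c(cells$x[i], cells$y[i]), c(nx, ny))) {
      occ[cells$x[i], cells$y[i]] <- 0L
      occ[nx, ny] <- i
      cells$x[i] <- nx; cells$y[i] <- ny
    }
    cells$persistence[i] <- cells$persistence[i] - 1L
  }
  list(cells = cells[!gone, , drop = FALSE], efflux = sum(gone))
}

#' One tick of T-cell influx
#'
#' Draws a Poisson number of entrants with per-tick mean
#' `influxRate * nResident / 1440` and places them as naive, generation-0,
#' age-0 cells at uniformly random free boundary sites.
#'
#' @param nResident current T-cell count in the tissue
#' @param config a [SimConfig-class]
#' @param tissue a [Tissue-class]
#' @param cells existing cell records (their sites are avoided)
#' @return records of the new entrants (possibly zero rows)
#' @export
influxCells <- function(nResident, config, tissue, cells = newTCells(integer(), integer())) {
  lambda <- config@influxRate * nResident / 1440
  n <- rpois(1, lambda)
  if (n == 0) return(newTCells(integer(), integer()))
  W <- tissue@gridWidth; H <- tissue@gridHeight
  bx <- c(1:W, 1:W, rep(1L, H - 2L), rep(W, H - 2L))
  by <- c(rep(1L, W), rep(H, W), 2:(H - 1L), 2:(H - 1L))
  occ <- .occupancy(tissue, cells)
  free <- tissue@betaGrid[cbind(bx, by)] == 0L & occ[cbind(bx, by)] == 0L
  bx <- bx[free]; by <- by[free]
  n <- min(n, length(bx))
  pick <- sample.int(length(bx), n)
  newTCells(bx[pick], by[pick], subset = "naive")
}

#' One tick of basement-membrane degradation
#'
#' Every membrane site with remaining strength loses `k` strength-minutes,
#' where `k` is the number of effector cells in its Moore neighbourhood
#' (co-located cells included); values floor at zero. A site at zero is an
#' opening and stays permanently passable; the membrane is never repaired.
#'
#' @param tissue a [Tissue-class]
#' @param cells T-cell records (only effectors degrade)
#' @return the updated tissue
#' @export
degradeMembrane <- function(tissue, cells) {
  eff <- cells[cells$subset == "effector", , drop = FALSE]
  if (nrow(eff) == 0) return(tissue)
  W <- tissue@gridWidth; H <- tissue@gridHeight
  pressure <- matrix(0, W, H)
  for (i in seq_len(nrow(eff))) {
    xs <- max(1, eff$x[i] - 1):min(W, eff$x[i] + 1)
    ys <- max(1, eff$y[i] - 1):min(H, eff$y[i] + 1)
    pressure[xs, ys] <- pressure[xs, ys] + 1
  }
  m <- tissue@membraneGrid
  idx <- !is.na(m) & m > 0 & pressure > 0
  m[idx] <- pmax(0, m[idx] - pressure[idx])
  tissue@membraneGrid <- m
  tissue
}

# is the Beta cell at site b=(x,y) conjugable by an effector at e=(x,y)?
.conjugable <- function(tissue, e, b) {
  if (tissue@interiorGrid[b[1], b[2]] == 0L) return(TRUE)
  if (tissue@interiorGrid[e[1], e[2]] > 0L) return(TRUE)
  m <- tissue@membraneGrid[e[1], e[2]]
  !is.na(m) && m <= 0
}

#' Conjugate formation and killing
#'
#' Each effector with spare conjugate capacity (at most `maxConjugates`
#' simultaneous engagements) that has at least one reachable Beta cell in its
#' Moore neighbourhood forms conjugates with up to capacity distinct targets,
#' chosen uniformly at random. Beta cells on the original islet footprint are
#' reachable only by effectors inside the islet or on an opened membrane
#' site; regrowth outside the footprint is always reachable. The kill is
#' decided once, at formation, with probability `killProb`; killed Beta cells
#' are removed immediately while the conjugate persists for `conjDuration`
#' minutes. Effectors are processed in randomised order, so several effectors
#' may engage one Beta cell in the same tick until it is killed.
#'
#' @param cells T-cell records
#' @param tissue a [Tissue-class]
#' @param config a [SimConfig-class]
#' @return list: `cells`, `tissue`, `kills` (count), `conjugates` (count),
#'   `attacked` (islet ids with a conjugated Beta cell)
#' @export
formConjugates <- function(cells, tissue, config) {
  kills <- 0L; conj <- 0L
  attacked <- integer()
  effIdx <- which(cells$subset == "effector")
  for (i in effIdx[sample.int(length(effIdx))]) {
    capacity <- config@maxConjugates -
      (cells$conj1[i] > 0) - (cells$conj2[i] > 0)
    if (capacity <= 0) next
    nx <- cells$x[i] + .DX; ny <- cells$y[i] + .DY
    ok <- nx >= 1 & nx <= tissue@gridWidth & ny >= 1 & ny <= tissue@gridHeight
    cand <- which(ok)
    cand <- cand[tissue@betaGrid[cbind(nx[cand], ny[cand])] > 0L]
    cand <- cand[vapply(cand, function(d)
      .conjugable(tissue, c(cells$x[i], cells$y[i]), c(nx[d], ny[d])),
      logical(1))]
    if (length(cand) == 0) next
    take <- cand[sample.int(length(cand))][seq_len(min(capacity, length(cand)))]
    for (d in take) {
      conj <- conj + 1L
      attacked <- union(attacked, tissue@betaGrid[nx[d], ny[d]])
      if (runif(1) < config@killProb) {
        tissue@betaGrid[nx[d], ny[d]] <- 0L
        kills <- kills + 1L
      }
      if (cells$conj1[i] == 0) cells$conj1[i] <- config@conjDuration
      else cells$conj2[i] <- config@conjDuration
    }
  }
  list(cells = cells, tissue = tissue, kills = kills, conjugates = conj,
       attacked = attacked)
}

#' Conjugate countdown
#'
#' Decrements every active conjugate's remaining time by one minute; expired
#' conjugates free the effector's capacity and mobility.
#'
#' @param cells T-cell records
#' @return updated records
#' @export
tickConjugates <- function(cells) {
  cells$conj1 <- pmax(0L, cells$conj1 - 1L)
  cells$conj2 <- pmax(0L, cells$conj2 - 1L)
  cells
}

# subset of one division product
.productSubset <- function(generation, config) {
  if (generation >= config@memoryDiffGeneration &&
      runif(1) < config@memoryDiffProb) "memory" else "effector"
}

#' One tick of activation and generation-tracked proliferation
#'
#' Non-cycling naive cells and unengaged non-cycling effector cells with a
#' Beta cell in their Moore neighbourhood enter the fast cell cycle with a
#' fresh timer. Cycling cells in contact (and not conjugated) count their
#' timer down; at zero the cell divides: parent and daughter both advance one
#' generation, restart at age 0, and each product independently becomes a
#' memory cell with probability `memoryDiffProb` from generation
#' `memoryDiffGeneration` on (effector otherwise). The daughter occupies a
#' uniformly random free Moore-neighbourhood site; division is deferred while
#' none is free. The timer pauses when contact is lost and resumes on
#' re-contact.
#'
#' @param cells T-cell records
#' @param tissue a [Tissue-class]
#' @param config a [SimConfig-class]
#' @return list: `cells` (with daughters appended), `divisions` (count)
#' @export
activateAndProliferate <- function(cells, tissue, config) {
  occ <- .occupancy(tissue, cells)
  divisions <- 0L
  n0 <- nrow(cells)
  for (i in sample.int(n0)) {
    if (!cells$cycling[i]) next
    if (cells$cycleTimer[i] > 0)
      cells$cycleTimer[i] <- cells$cycleTimer[i] - 1L
    if (cells$cycleTimer[i] > 0) next
    nx <- cells$x[i] + .DX; ny <- cells$y[i] + .DY
    ok <- nx >= 1 & nx <= tissue@gridWidth & ny >= 1 & ny <= tissue@gridHeight
    free <- which(ok)
    free <- free[vapply(free, function(d)
      .canOccupy(tissue, occ, c(cells$x[i], cells$y[i]), c(nx[d], ny[d])),
      logical(1))]
    if (length(free) == 0) next               # deferred one tick
    d <- free[sample.int(length(free), 1)]
    g <- cells$generation[i] + 1L
    # one antigen encounter commits the lineage to the programmed burst:
    # below the memory-eligible generation products re-enter the cycle
    # autonomously; later generations need renewed contact
    burst <- g < config@memoryDiffGeneration
    cells$generation[i] <- g
    cells$age[i] <- 0
    cells$subset[i] <- .productSubset(g, config)
    cells$cycling[i] <- burst && cells$subset[i] == "effector"
    cells$cycleTimer[i] <- if (cells$cycling[i]) config@divisionCycleTime else 0L
    daughter <- newTCells(nx[d], ny[d], subset = .productSubset(g, config),
                          generation = g)
    if (burst && daughter$subset == "effector") {
      daughter$cycling <- TRUE
      daughter$cycleTimer <- config@divisionCycleTime
    }
    occ[nx[d], ny[d]] <- nrow(cells) + 1L
    cells <- rbind(cells, daughter)
    divisions <- divisions + 1L
  }
  # activation pass (newly created products included)
  for (i in seq_len(nrow(cells))) {
    if (cells$cycling[i] || cells$subset[i] == "memory") next
    engaged <- cells$subset[i] == "effector" &&
      (cells$conj1[i] > 0 || cells$conj2[i] > 0)
    if (engaged || .antigenContact(tissue, cells$x[i], cells$y[i])) {
      cells$cycling[i] <- TRUE
      cells$cycleTimer[i] <- config@divisionCycleTime
    }
  }
  list(cells = cells, divisions = divisions)
}

#' Attack triggering and Beta-cell regeneration
#'
#' An islet's attack flag is set permanently the first tick any T cell
#' occupies one of its membrane or interior sites (conjugation of one of its
#' Beta cells also triggers it, see [formConjugates()]). Once triggered, each
#' living Beta cell of the islet divides with per-tick probability
#' `betaRegenRate / 1440`; the daughter occupies a uniformly random site of
#' the mother's Moore neighbourhood that holds no Beta or T cell (growth may
#' extend past the original islet footprint). Division is skipped when no
#' neighbour is free.
#'
#' @param tissue a [Tissue-class]
#' @param cells T-cell records
#' @param config a [SimConfig-class]
#' @param triggered logical vector of per-islet attack flags
#' @return list: `tissue`, `triggered`, `births` (count)
#' @export
triggerAndRegenerate <- function(tissue, cells, config,
                                 triggered = logical(nIslets(tissue))) {
  if (nrow(cells)) {
    # a T cell on a membrane or interior site, or an effector engaged at the
    # ring, marks the islet as attacked; conjugation triggers via
    # formConjugates()
    ids <- tissue@membraneIslet[cbind(cells$x, cells$y)]
    inner <- tissue@interiorGrid[cbind(cells$x, cells$y)]
    triggered[unique(c(ids[ids > 0L], inner[inner > 0L]))] <- TRUE
    eff <- cells[cells$subset == "effector", , drop = FALSE]
    for (i in seq_len(nrow(eff))) {
      xs <- max(1, eff$x[i] - 1):min(tissue@gridWidth, eff$x[i] + 1)
      ys <- max(1, eff$y[i] - 1):min(tissue@gridHeight, eff$y[i] + 1)
      m <- tissue@membraneGrid[xs, ys]
      id <- tissue@membraneIslet[xs, ys][!is.na(m) & m > 0]
      triggered[unique(id)] <- TRUE
    }
  }
  births <- 0L
  if (config@betaRegenRate > 0 && any(triggered)) {
    p <- config@betaRegenRate / 1440
    occ <- .occupancy(tissue, cells)
    sites <- which(tissue@betaGrid > 0L)
    W <- tissue@gridWidth; H <- tissue@gridHeight
    for (s in sites) {
      id <- tissue@betaGrid[s]
      if (!triggered[id]) next
      if (runif(1) >= p) next
      x <- (s - 1L) %% W + 1L; y <- (s - 1L) %/% W + 1L
      nx <- x + .DX; ny <- y + .DY
      ok <- nx >= 1 & nx <= W & ny >= 1 & ny <= H
      free <- which(ok)
      free <- free[tissue@betaGrid[cbind(nx[free], ny[free])] == 0L &
                   occ[cbind(nx[free], ny[free])] == 0L]
      if (length(free) > 0) {
        d <- free[sample.int(length(free), 1)]
        tissue@betaGrid[nx[d], ny[d]] <- id
        births <- births + 1L
        next
      }
      # crowded: growth pressure pushes the newborn along a straight line
      # of Beta cells to the nearest free site (it emerges at the surface);
      # skip only if no such path exists
      d <- sample.int(8L, 1)
      L <- -1L
      for (step in 1:24) {
        px <- x + .DX[d] * step; py <- y + .DY[d] * step
        if (px < 1 || px > W || py < 1 || py > H) break
        if (occ[px, py] != 0L) break
        if (tissue@betaGrid[px, py] == 0L) { L <- step; break }
      }
      if (L < 0) next
      tissue@betaGrid[x + .DX[d] * L, y + .DY[d] * L] <- id
      births <- births + 1L
    }
  }
  list(tissue = tissue, triggered = triggered, births = births)
}
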