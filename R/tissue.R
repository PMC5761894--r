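# site offsets of a rasterised disk: a site belongs to the islet when its
# centre lies within the radius
.diskOffsets <- function(radius) {
  R <- ceiling(radius)
  g <- expand.grid(dx = -R:R, dy = -R:R)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# Moore dilation of an offset set, as unique (dx, dy) pairs
.dilateOffsets <- function(off) {
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  out <- unique(data.frame(
    dx = rep(off$dx, each = nrow(shifts)) + rep(shifts$sx, nrow(off)),
    dy = rep(off$dy, each = nrow(shifts)) + rep(shifts$sy, nrow(off))
  ))
  out
}

# the membrane ring: non-islet sites 8-adjacent to islet sites
.ringOffsets <- function(disk) {
  dil <- .dilateOffsets(disk)
  key <- function(d) paste(d$dx, d$dy)
  dil[!key(dil) %in% key(disk), , drop = FALSE]
}

.densityRange <- function(config) {
  rng <- config@densityRange
  if (length(rng) == 2 && !anyNA(rng)) rng
  else .DENSITY_RANGES[[config@isletDensityClass]]
}

#' Generate a synthetic pancreatic tissue section
#'
#' Places non-overlapping circular islets with diameters drawn uniformly from
#' the configured range at rejection-sampled random centres, one at a time,
#' until the islet area fraction reaches a target drawn uniformly within the
#' density-class range. Every islet site holds one Beta cell; every islet gets
#' a one-site-thick basement-membrane ring (the non-islet sites 8-adjacent to
#' islet sites), each ring site initialised to the configured strength.
#' Islets including their rings are kept at least one empty site apart and at
#' least one site away from the tissue boundary.
#'
#' Uses the current R random stream; call `set.seed()` first for a
#' reproducible layout.
#'
#' @param config a [SimConfig-class]
#' @param maxAttempts placement attempts before giving up with an error
#' @return a [Tissue-class]; achieved area fraction and islet count are in
#'   its `areaFraction` slot and `islets` table
#' @examples
#' set.seed(1)
#' tis <- generateTissue(simConfig())
#' tis
#' @export
generateTissue <- function(config, maxAttempts = 5000L) {
  W <- config@gridWidth; H <- config@gridHeight
  rng <- .densityRange(config)
  target <- if (diff(rng) > 0) runif(1, rng[1], rng[2]) else rng[1]

  betaGrid <- matrix(0L, W, H)
  membraneGrid <- matrix(NA_real_, W, H)
  membraneIslet <- matrix(0L, W, H)
  interiorGrid <- matrix(0L, W, H)
  blocked <- matrix(FALSE, W, H)
  islets <- data.frame(id = integer(), cx = integer(), cy = integer(),
                       radius = numeric(), nBeta = integer())

  frac <- 0
  id <- 0L
  attempts <- 0L
  nSites <- W * H
  while (frac < target) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts) {
      # no further islet fits under the class ceiling; the layout is valid
      # as long as the achieved fraction already lies inside the class range
      if (frac >= rng[1]) break
      stop("tissue placement failed: density target ", signif(target, 3),
           " not attainable after ", maxAttempts, " attempts")
    }
    diam <- runif(1, config@isletDiameterRange[1], config@isletDiameterRange[2])
    r <- diam / 2 / config@siteSize
    disk <- .diskOffsets(r)
    ring <- .ringOffsets(disk)
    cx <- sample.int(W, 1)
    cy <- sample.int(H, 1)
    bx <- cx + disk$dx; by <- cy + disk$dy
    rx <- cx + ring$dx; ry <- cy + ring$dy
    ax <- c(bx, rx); ay <- c(by, ry)
    # islet plus ring stays off the boundary row/column
    if (min(ax) < 2 || min(ay) < 2 || max(ax) > W - 1 || max(ay) > H - 1) next
    if (any(blocked[cbind(ax, ay)])) next
    newFrac <- frac + nrow(disk) / nSites
    if (newFrac > rng[2]) next
    id <- id + 1L
    betaGrid[cbind(bx, by)] <- id
    interiorGrid[cbind(bx, by)] <- id
    membraneGrid[cbind(rx, ry)] <- config@membraneStrength
    membraneIslet[cbind(rx, ry)] <- id
    dil <- .dilateOffsets(rbind(disk, ring))
    dx <- pmin(pmax(cx + dil$dx, 1), W)
    dy <- pmin(pmax(cy + dil$dy, 1), H)
    blocked[cbind(dx, dy)] <- TRUE
    islets <- rbind(islets, data.frame(id = id, cx = cx, cy = cy, radius = r,
                                       nBeta = nrow(disk)))
    frac <- newFrac
    attempts <- 0L   # the stall budget is per islet
  }

  new("Tissue", gridWidth = W, gridHeight = H, islets = islets,
      betaGrid = betaGrid, membraneGrid = membraneGrid,
      membraneIslet = membraneIslet, interiorGrid = interiorGrid,
      areaFraction = frac, membraneStrength = config@membraneStrength)
}

#' Construct T-cell records
#'
#' Builds the standard T-cell data.frame used across the package: one row per
#' cell with position, subset, age, generation, motility state and conjugate
#' bookkeeping.
#'
#' @param x,y 1-based site coordinates
#' @param subset `"naive"`, `"effector"` or `"memory"` (recycled)
#' @param age age in minutes
#' @param generation divisions since lineage start
#' @param direction lattice direction index 0--7
#' @param persistence remaining persistence minutes
#' @param cycling in the fast cell cycle?
#' @param cycleTimer remaining minutes of the current cycle
#' @param conj1,conj2 remaining minutes of up to two conjugates (0 = none)
#' @return data.frame of T-cell records
#' @export
newTCells <- function(x, y, subset = "naive", age = 0, generation = 0L,
                      direction = 0L, persistence = 0L, cycling = FALSE,
                      cycleTimer = 0L, conj1 = 0L, conj2 = 0L) {
  n <- max(length(x), length(y))
  stopifnot(all(subset %in% .SUBSET_LEVELS))
  data.frame(x = as.integer(x), y = as.integer(y),
             subset = rep_len(as.character(subset), n),
             age = rep_len(as.numeric(age), n),
             generation = rep_len(as.integer(generation), n),
             direction = rep_len(as.integer(direction), n),
             persistence = rep_len(as.integer(persistence), n),
             cycling = rep_len(as.logical(cycling), n),
             cycleTimer = rep_len(as.integer(cycleTimer), n),
             conj1 = rep_len(as.integer(conj1), n),
             conj2 = rep_len(as.integer(conj2), n))
}

#' Place the initial T-cell inoculum
#'
#' Places exactly `nInitialTcells` cells at uniformly random free sites that
#' are neither islet nor membrane sites, no two cells sharing a site. The
#' subset split follows the configured effector:naive ratio
#' (see [effectorNaiveSplit()]); ages start at 0 and generations at 0.
#'
#' @param config a [SimConfig-class]
#' @param tissue a [Tissue-class]
#' @return data.frame of T-cell records (see [newTCells()])
#' @export
placeInitialTCells <- function(config, tissue) {
  n <- config@nInitialTcells
  free <- which(tissue@betaGrid == 0L & tissue@membraneIslet == 0L)
  if (length(free) < n)
    stop("not enough free sites to place ", n, " T cells")
  sites <- free[sample.int(length(free), n)]
  W <- tissue@gridWidth
  xs <- (sites - 1L) %% W + 1L
  ys <- (sites - 1L) %/% W + 1L
  split <- effectorNaiveSplit(config)
  subsets <- rep(c("effector", "naive"), c(split[["effector"]], split[["naive"]]))
  newTCells(xs, ys, subset = subsets)
}

#' @describeIn generateTissue islet count of a tissue
#' @param x a [Tissue-class]
#' @export
setMethod("nIslets", "Tissue", function(x) nrow(x@islets))

#' @describeIn generateTissue number of live Beta cells
#' @export
setMethod("betaCount", "Tissue", function(x) sum(x@betaGrid > 0L))

setMethod("show", "Tissue", function(object) {
  cat(sprintf("Tissue: %d x %d sites, %d islets, %d Beta cells (%.2f%% area)\n",
              object@gridWidth, object@gridHeight, nIslets(object),
              betaCount(object), 100 * object@areaFraction))
  m <- object@membraneGrid
  if (any(!is.na(m)))
    cat(sprintf("  membrane: %d ring sites, strength %g min\n",
                sum(!is.na(m)), object@membraneStrength))
})

#' Export a tissue as a plain-text grid dump
#'
#' Writes one character per site, row per grid y-line: `.` empty, `B` Beta
#' cell, `m` membrane ring, `o` opened membrane (strength 0).
#'
#' @param tissue a [Tissue-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTissueGrid <- function(tissue, path) {
  W <- tissue@gridWidth; H <- tissue@gridHeight
  ch <- matrix(".", W, H)
  ch[!is.na(tissue@membraneGrid) & tissue@membraneGrid > 0] <- "m"
  ch[!is.na(tissue@membraneGrid) & tissue@membraneGrid == 0] <- "o"
  ch[tissue@betaGrid > 0L] <- "B"
  lines <- vapply(seq_len(H), function(y) paste(ch[, y], collapse = ""),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Islet manifest as JSON
#'
#' One record per islet with id, centre, radius (sites) and Beta-cell area,
#' plus the achieved area fraction, for inspection and testing.
#'
#' @param tissue a [Tissue-class]
#' @param path optional output file; when `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to a file)
#' @export
isletManifest <- function(tissue, path = NULL) {
  manifest <- list(
    gridWidth = tissue@gridWidth, gridHeight = tissue@gridHeight,
    areaFraction = tissue@areaFraction, nIslets = nIslets(tissue),
    islets = tissue@islets
  )
  js <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
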