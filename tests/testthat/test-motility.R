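test_that("a free cell with persistence moves straight at one site per minute", {
  tis <- insulitisSim:::.syntheticTissue(50, 50)
  cfg <- simConfig()
  # direction 0 is +x; persistence 4 carries the cell 4 sites in 4 ticks
  cells <- newTCells(10, 10, subset = "naive", direction = 0L,
                     persistence = 4L)
  for (k in 1:4) cells <- stepCells(cells, tis, cfg)$cells
  expect_identical(c(cells$x, cells$y), c(14L, 10L))
  expect_identical(cells$persistence, 0L)
})

test_that("blocked steps waste the tick and efflux removes edge-leavers", {
  cfg <- simConfig()
  # target site holds a Beta cell: the mover stays put
  tis <- insulitisSim:::.syntheticTissue(
    20, 20, betaSites = data.frame(x = 11, y = 10, id = 1))
  cells <- newTCells(10, 10, subset = "naive", direction = 0L,
                     persistence = 3L)
  out <- stepCells(cells, tis, cfg)
  expect_identical(c(out$cells$x, out$cells$y), c(10L, 10L))
  # a T cell on the target site blocks likewise
  tis2 <- insulitisSim:::.syntheticTissue(20, 20)
  two <- newTCells(c(10, 11), 10, subset = "naive", direction = 0L,
                   persistence = c(3L, 0L))
  out2 <- stepCells(two[1, ], tis2, cfg)  # alone it moves
  expect_identical(out2$cells$x, 11L)
  # edge cell stepping outward is removed; an interior cell never is
  edge <- newTCells(20, 10, subset = "naive", direction = 0L, persistence = 2L)
  out3 <- stepCells(edge, tis2, cfg)
  expect_identical(nrow(out3$cells), 0L)
  expect_identical(out3$efflux, 1L)
  # brute-force check over many random edge walkers: removal count equals
  # the count of outward crossings
  set.seed(31)
  for (rep in 1:20) {
    n <- 12
    cells <- newTCells(sample(c(1L, 20L), n, TRUE),
                       sample.int(20L, n), subset = "naive",
                       direction = sample(0:7, n, TRUE),
                       persistence = 1L)
    cells <- cells[!duplicated(cells[, c("x", "y")]), ]
    dx <- insulitisSim:::.DX[cells$direction + 1L]
    dy <- insulitisSim:::.DY[cells$direction + 1L]
    outward <- cells$x + dx < 1 | cells$x + dx > 20 |
               cells$y + dy < 1 | cells$y + dy > 20
    out <- stepCells(cells, tis2, cfg)
    expect_identical(out$efflux, sum(outward))
  }
})

test_that("engine mean squared displacement matches an independent walk oracle", {
  # independent vectorised re-simulation of the persistent random walk
  # (free space, no collisions) as the reference
  msdOracle <- function(n, ticks, seed) {
    set.seed(seed)
    x <- numeric(n); y <- numeric(n)
    dir <- integer(n); pers <- integer(n)
    for (t in seq_len(ticks)) {
      redraw <- pers <= 0
      dir[redraw] <- sample.int(8L, sum(redraw), TRUE) - 1L
      pers[redraw] <- sample.int(4L, sum(redraw), TRUE)
      x <- x + insulitisSim:::.DX[dir + 1L]
      y <- y + insulitisSim:::.DY[dir + 1L]
      pers <- pers - 1L
    }
    mean(x^2 + y^2)
  }
  oracle <- msdOracle(20000, 60, 11)

  # engine walkers spaced far apart so collisions are negligible
  tis <- insulitisSim:::.syntheticTissue(1000, 1000)
  g <- expand.grid(x = seq(100, 900, by = 40), y = seq(100, 900, by = 40))
  cells <- newTCells(g$x, g$y, subset = "naive")
  cfg <- simConfig(influxRate = 0, naiveLifespan = 1e9)
  set.seed(12)
  res <- runEngine(tis, cells, cfg, ticks = 60, checkInvariants = FALSE)
  cc <- res$state$cells
  msd <- mean((cc$x - g$x)^2 + (cc$y - g$y)^2)
  # agreement within ~3 standard errors at 441 engine walkers
  expect_lt(abs(msd - oracle) / oracle, 0.2)
})

test_that("influx draws match the stated daily rate and entrant contract", {
  cfg <- simConfig()
  tis <- insulitisSim:::.syntheticTissue(200, 200)
  # no residents, no entrants
  set.seed(1)
  expect_identical(nrow(influxCells(0, cfg, tis)), 0L)
  # for a fixed resident pool the daily mean entrant count is 1.7% of it
  set.seed(2)
  N <- 144000
  perTick <- replicate(2000, nrow(influxCells(N, cfg, tis)))
  dailyMean <- mean(perTick) * 1440
  se <- sd(perTick) * 1440 / sqrt(length(perTick))
  expect_lt(abs(dailyMean - 0.017 * N), 4 * se)
  # entrants are naive, generation 0, age 0, on the boundary
  set.seed(3)
  ent <- do.call(rbind, replicate(300, influxCells(2e5, cfg, tis),
                                  simplify = FALSE))
  expect_gt(nrow(ent), 100)
  expect_true(all(ent$subset == "naive"))
  expect_true(all(ent$age == 0 & ent$generation == 0L))
  onEdge <- ent$x %in% c(1L, 200L) | ent$y %in% c(1L, 200L)
  expect_true(all(onEdge))
})
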