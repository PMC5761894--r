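test_that("the same seed and configuration reproduce a run bit for bit", {
  cfg <- simConfig(durationDays = 3, membraneStrength = 1440,
                   gridWidth = 100L, gridHeight = 100L,
                   nInitialTcells = 6L)
  a <- runSimulation(cfg, seed = 21)
  b <- runSimulation(cfg, seed = 21)
  expect_identical(series(a), series(b))
  expect_identical(eventCounts(a), eventCounts(b))
  c <- runSimulation(cfg, seed = 22)
  expect_false(identical(series(a), series(c)))
})

test_that("a zero-day horizon yields only the initialisation record", {
  run <- runSimulation(simConfig(durationDays = 0), seed = 3)
  expect_identical(nrow(series(run)), 1L)
  expect_identical(series(run)$day, 0)
  expect_equal(series(run)$beta, run@initialBeta)
})

test_that("one tick on a hand-built fixture decrements the membrane by one", {
  # 5x5 grid, one membrane site, one frozen adjacent effector
  tis <- insulitisSim:::.syntheticTissue(
    5, 5, membraneSites = data.frame(x = 3, y = 3, id = 1), strength = 50)
  cells <- newTCells(4, 3, subset = "effector")
  cfg <- simConfig(motility = FALSE, influxRate = 0)
  set.seed(1)
  res <- runEngine(tis, cells, cfg, ticks = 1)
  expect_equal(res$state$tissue@membraneGrid[3, 3], 49)
  # nothing else changed; the engaged effector holds position and its
  # lifespan clock pauses while engaged
  expect_identical(nrow(res$state$cells), 1L)
  expect_equal(res$state$cells$age, 0)
})

test_that("population bookkeeping balances every recorded day", {
  set.seed(33)
  cfg <- simConfig(gridWidth = 100L, gridHeight = 100L,
                   membraneStrength = 1440, durationDays = 8,
                   nInitialTcells = 6L, densityRange = c(0.02, 0.05))
  run <- runSimulation(cfg, seed = 33, checkInvariants = TRUE)
  s <- series(run)
  tcells <- s$naive + s$effector + s$memory
  # (division births + influx) - (deaths + efflux) equals the net change
  expect_equal(diff(tcells),
               diff(s$divisions) + diff(s$influx) -
               diff(s$deaths) - diff(s$efflux))
  # (regeneration births) - (kills) equals the net Beta change
  expect_equal(diff(s$beta), diff(s$regenBirths) - diff(s$kills))
})

test_that("occupancy invariants hold through a long randomised stress run", {
  set.seed(55)
  cfg <- simConfig(gridWidth = 60L, gridHeight = 60L,
                   membraneStrength = 720, durationDays = 7,
                   densityRange = c(0.02, 0.06), nInitialTcells = 9L,
                   betaRegenRate = 0.05)
  tissue <- generateTissue(cfg)
  cells <- placeInitialTCells(cfg, tissue)
  state <- insulitisSim:::.engineState(tissue, cells)
  # the engine audits occupancy/census coherence throughout and at the end
  expect_no_error(
    insulitisSim:::.cpp_run(state, insulitisSim:::.engineParams(cfg),
                            nTicks = 10000L, recordEvery = 1000L,
                            checkInvariants = TRUE, returnState = FALSE,
                            earlyStop = FALSE))
})

test_that("an empty tissue with no T cells stays frozen (conservation)", {
  cfg <- simConfig(densityRange = c(0, 0), nInitialTcells = 0L,
                   durationDays = 1)
  run <- runSimulation(cfg, seed = 5)
  s <- series(run)
  expect_true(all(s$beta == 0))
  expect_true(all(s$naive + s$effector + s$memory == 0))
  expect_true(run@earlyStopped)
})

test_that("ensembles replay identically and reduce to single runs", {
  cfg <- simConfig(durationDays = 2, gridWidth = 80L, gridHeight = 80L,
                   membraneStrength = 1440, densityRange = c(0.02, 0.05))
  e1 <- runEnsemble(cfg, nReplicates = 3, baseSeed = 40)
  e2 <- runEnsemble(cfg, nReplicates = 3, baseSeed = 40)
  expect_identical(e1@runs, e2@runs)
  expect_identical(e1@seeds, 40:42)
  single <- runSimulation(cfg, seed = 41)
  expect_identical(e1@runs[[2]], series(single))
  # incremental persistence
  dir <- withr::local_tempdir()
  runEnsemble(cfg, nReplicates = 2, baseSeed = 40, outDir = dir)
  files <- list.files(dir, pattern = "^timeseries_\\d+\\.csv$")
  expect_setequal(files, c("timeseries_40.csv", "timeseries_41.csv"))
  back <- read.csv(file.path(dir, "timeseries_41.csv"))
  expect_equal(back$beta, series(single)$beta)
})
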