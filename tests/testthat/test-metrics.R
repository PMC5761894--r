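# build a synthetic ensemble from explicit beta trajectories
syntheticRuns <- function(betaRows) {
  lapply(seq_len(nrow(betaRows)), function(i) {
    data.frame(day = seq_len(ncol(betaRows)) - 1, beta = betaRows[i, ],
               naive = 0, effector = 0, memory = 0)
  })
}

test_that("box statistics use linear quartiles and 1.5 IQR fences", {
  b <- boxStats(c(1, 2, 3, 4, 5))
  expect_equal(unname(b[c("q1", "median", "q3")]), c(2, 3, 4))
  expect_identical(unname(b["nOutliers"]), 0)
  expect_equal(unname(b[c("whiskerLow", "whiskerHigh")]), c(1, 5))
  b2 <- boxStats(c(1, 1, 1, 1, 100))
  expect_identical(unname(b2["nOutliers"]), 1)
  expect_equal(unname(b2["whiskerHigh"]), 1)
  # degenerate sample: quartiles and whiskers all coincide
  b3 <- boxStats(rep(7, 10))
  expect_true(all(b3[c("q1", "median", "q3", "whiskerLow", "whiskerHigh")] == 7))
  expect_error(boxStats(numeric(0)), "empty")
})

test_that("per-day quartile summaries require at least two replicates", {
  runs <- syntheticRuns(rbind(c(10, 8, 6), c(12, 9, 3)))
  s <- quartileSummary(runs, what = "beta")
  expect_identical(nrow(s), 3L)
  expect_equal(s$median, c(11, 8.5, 4.5))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_error(quartileSummary(runs[1], what = "beta"), "at least 2")
})

test_that("half-loss day scans the median Beta series against half the start", {
  # the synthetic median series 100, 100, 60, 49, 10 crosses on day 3
  runs <- syntheticRuns(rbind(c(100, 100, 60, 49, 10),
                              c(100, 100, 60, 49, 10),
                              c(100, 100, 60, 49, 10)))
  expect_equal(halfLossDay(runs), 3)
  # a constant series never reaches it
  runs2 <- syntheticRuns(rbind(c(50, 50, 50), c(60, 60, 60)))
  expect_true(is.na(halfLossDay(runs2)))
  # exactly half counts as reached
  runs3 <- syntheticRuns(rbind(c(100, 50), c(100, 50)))
  expect_equal(halfLossDay(runs3), 1)
})

test_that("the inflammation window brackets a synthetic ramp", {
  # flat at 100 to day 10, linear fall to 40 over days 10-30, flat after
  traj <- c(rep(100, 11), seq(97, 40, length.out = 20), rep(40, 10))
  runs <- syntheticRuns(rbind(traj, traj))
  w <- inflammationWindow(runs)
  expect_equal(unname(w["onset"]), 12)   # first day below 95 on this ramp
  expect_true(w["end"] >= 30 && w["end"] <= 32)
  # no attack, no window
  quiet <- syntheticRuns(rbind(rep(100, 20), rep(100, 20)))
  expect_true(is.na(inflammationWindow(quiet)[1]))
})

test_that("half-loss day is monotone under attack intensity across ensembles", {
  # stronger attacks (faster median decline) never report a later day
  mk <- function(rate) {
    traj <- pmax(0, 100 - rate * (0:40))
    syntheticRuns(rbind(traj, traj + 2, traj - 2))
  }
  days <- vapply(c(2, 5, 10), function(r) halfLossDay(mk(r)), numeric(1))
  expect_true(all(diff(days) <= 0))
})

test_that("ensemble summary files carry box statistics and derived metrics", {
  set.seed(61)
  cfg <- simConfig(durationDays = 2, gridWidth = 80L, gridHeight = 80L,
                   membraneStrength = 1440, densityRange = c(0.02, 0.05))
  ens <- runEnsemble(cfg, nReplicates = 3, baseSeed = 60)
  summ <- summarizeEnsemble(ens)
  expect_setequal(unique(summ$cellType), c("beta", "naive", "effector", "memory"))
  expect_identical(nrow(summ), 4L * 3L)
  dir <- withr::local_tempdir()
  metrics <- writeEnsembleSummary(ens, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  js <- jsonlite::fromJSON(file.path(dir, "metrics.json"))
  expect_equal(js$nReplicates, 3)
  expect_equal(js$medianInitialBeta, metrics$medianInitialBeta)
  tab <- scenarioTable(list(demo = ens))
  expect_identical(tab$scenario, "demo")
  expect_equal(tab$membraneStrength, 1440)
})
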