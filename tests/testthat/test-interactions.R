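test_that("conjugation respects capacity and picks targets uniformly", {
  cfg <- simConfig()
  # effector surrounded by 3 exposed Beta cells, capacity 2
  tis <- insulitisSim:::.syntheticTissue(
    9, 9, betaSites = data.frame(x = c(4, 5, 6), y = 6, id = 1))
  base <- newTCells(5, 5, subset = "effector")
  picks <- integer(0)
  set.seed(18)
  cfgKill <- simConfig(killProb = 1)
  for (k in 1:900) {
    out <- formConjugates(base, tis, cfgKill)
    expect_identical(out$conjugates, 2L)          # exactly 2 of 3 engaged
    expect_identical(out$kills, 2L)
    dead <- which(out$tissue@betaGrid == 0L & tis@betaGrid > 0L)
    picks <- c(picks, dead)
  }
  # uniform choice of 2 among the 3 candidates: each target is engaged
  # (and killed, at probability 1) in 2/3 of rounds
  freq <- table(factor(picks, levels = which(tis@betaGrid > 0L)))
  for (f in freq) expect_true(statisticalCheck(f, 900, 2 / 3, alpha = 0.001))
  # capacity already used: no new conjugates
  busy <- newTCells(5, 5, subset = "effector", conj1 = 30L, conj2 = 10L)
  out2 <- formConjugates(busy, tis, cfg)
  expect_identical(out2$conjugates, 0L)
})

test_that("kill probability zero never kills; probability one kills on contact", {
  tis <- insulitisSim:::.syntheticTissue(
    9, 9, betaSites = data.frame(x = 5, y = 6, id = 1))
  eff <- newTCells(5, 5, subset = "effector")
  set.seed(4)
  none <- formConjugates(eff, tis, simConfig(killProb = 0))
  expect_identical(none$kills, 0L)
  expect_identical(none$conjugates, 1L)    # engaged but never lethal
  expect_identical(none$attacked, 1L)      # conjugation still marks the islet
  # the deterministic fixture: certain kill on the tick of first contact
  fx <- buildFixture("certain_kill")
  set.seed(5)
  res <- runFixture(fx, ticks = 1)
  expect_equal(res$series$beta, c(1, 0))
  expect_equal(unname(res$events["kills"]), 1)
})

test_that("membrane-protected Beta cells are not conjugable from outside", {
  i1 <- insulitisSim:::.fixtureIslet(10, 10, 4, 1L)
  tis <- insulitisSim:::.syntheticTissue(20, 20, betaSites = i1$beta,
                                         interiorSites = i1$beta,
                                         membraneSites = i1$ring,
                                         strength = 1440)
  ringTop <- i1$ring[which.max(i1$ring$y), ]
  onRing <- newTCells(ringTop$x, ringTop$y, subset = "effector")
  set.seed(6)
  out <- formConjugates(onRing, tis, simConfig(killProb = 1))
  expect_identical(out$conjugates, 0L)   # intact ring blocks the contact
  # the same position attacks freely once that ring site is opened
  tis2 <- tis
  tis2@membraneGrid[ringTop$x, ringTop$y] <- 0
  out2 <- formConjugates(onRing, tis2, simConfig(killProb = 1))
  expect_gt(out2$conjugates, 0L)
})

test_that("kill fraction over 10^4 conjugates sits in the exact 99% binomial region", {
  kills <- 0; n <- 0
  for (seed in 1:4) {
    fx <- buildFixture("kill_statistics", pairs = 50L)
    set.seed(seed)
    res <- runFixture(fx, ticks = 1, returnState = FALSE)
    kills <- kills + unname(res$events["kills"])
    n <- n + unname(res$events["conjugates"])
  }
  expect_identical(n, 4 * 2500)
  expect_true(statisticalCheck(kills, n, 0.55, alpha = 0.01))
})

test_that("conjugates immobilise the effector for exactly 90 minutes", {
  # an effector with a fresh conjugate and no further targets stays put
  # through tick 89 and moves again once the conjugate expires
  tis <- insulitisSim:::.syntheticTissue(31, 31)
  cells <- newTCells(16, 16, subset = "effector", conj1 = 90L,
                     direction = 0L, persistence = 100L)
  cfg <- simConfig(influxRate = 0, effectorLifespan = 1e9)
  set.seed(8)
  res <- runEngine(tis, cells, cfg, ticks = 89)
  expect_identical(c(res$state$cells$x, res$state$cells$y), c(16L, 16L))
  set.seed(8)
  res2 <- runEngine(tis, cells, cfg, ticks = 95)
  expect_false(all(c(res2$state$cells$x, res2$state$cells$y) == 16L))
  # countdown oracle on records
  cells2 <- newTCells(16, 16, subset = "effector", conj1 = 37L, conj2 = 11L)
  out <- cells2
  for (k in 1:11) out <- tickConjugates(out)
  expect_identical(c(out$conj1, out$conj2), c(26L, 0L))
})

test_that("memory differentiation hits 20% from generation 8 and never below", {
  # products at generations 1..7 are always effector
  fx <- buildFixture("memory_statistics", pairs = 30L)
  fx$cells$generation <- 0L
  set.seed(9)
  res <- runFixture(fx, ticks = 6 * 3)  # three divisions: generations 1-3
  cc <- res$state$cells
  expect_true(all(cc$subset == "effector"))
  expect_true(all(cc$generation <= 3))
  # generation-8 products draw memory at 20%: >= 10^4 independent draws
  draws <- 0; mem <- 0
  for (seed in 1:3) {
    fx <- buildFixture("memory_statistics", pairs = 50L)
    set.seed(seed)
    res <- runFixture(fx, ticks = 6, returnState = FALSE)
    draws <- draws + 2 * unname(res$events["divisions"])
    mem <- mem + unname(res$events["memoryDiff"])
  }
  expect_gte(draws, 10000)
  expect_true(statisticalCheck(mem, draws, 0.2, alpha = 0.01))
})

test_that("regeneration is gated on the attack trigger", {
  g <- data.frame(x = c(10, 30), y = c(10, 30), id = 1:2)
  tis <- insulitisSim:::.syntheticTissue(40, 40, betaSites = g,
                                         interiorSites = g)
  cfg <- simConfig(betaRegenRate = 0.05)
  # untriggered islets never divide, at any rate
  set.seed(10)
  out <- triggerAndRegenerate(tis, newTCells(integer(), integer()), cfg,
                              triggered = c(FALSE, FALSE))
  expect_identical(out$births, 0L)
  expect_false(any(out$triggered))
  # a T cell on an interior site triggers that islet permanently
  tis2 <- tis
  tis2@betaGrid[10, 10] <- 0L   # freed site
  invader <- newTCells(10, 10, subset = "naive")
  out2 <- triggerAndRegenerate(tis2, invader, cfg, triggered = c(FALSE, FALSE))
  expect_identical(out2$triggered, c(TRUE, FALSE))
  # with regeneration disabled the Beta count is monotone non-increasing
  set.seed(11)
  run <- runSimulation(simConfig(gridWidth = 60L, gridHeight = 60L,
                                 betaRegenRate = 0, durationDays = 4,
                                 densityRange = c(0.02, 0.05),
                                 membraneStrength = 1440,
                                 nInitialTcells = 4L))
  expect_true(all(diff(series(run)$beta) <= 0))
})

test_that("triggered regrowth matches the branching-process mean", {
  # 400 isolated pre-triggered single-cell islets, 10 days at 5%/day:
  # expected mean 400 * (1 + 0.05/1440)^14400 = 659.5
  fx <- buildFixture("regrowth_only")
  set.seed(12)
  res <- runFixture(fx, ticks = 10 * 1440, recordEvery = 1440,
                    returnState = FALSE)
  expected <- 400 * (1 + 0.05 / 1440)^(10 * 1440)
  # ~3 sigma of the branching-process variance across 400 founders
  expect_lt(abs(res$series$beta[11] - expected), 65)
  # growth is monotone with no attackers
  expect_true(all(diff(res$series$beta) >= 0))
})
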