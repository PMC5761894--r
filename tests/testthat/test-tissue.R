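test_that("generated tissues respect geometry, density class and Beta accounting", {
  for (cls in c("low", "medium", "high")) {
    rng <- insulitisSim:::.DENSITY_RANGES[[cls]]
    for (seed in 1:5) {
      set.seed(seed * 97)
      cfg <- simConfig(isletDensityClass = cls)
      tis <- generateTissue(cfg)
      # islet diameters stay within 100-160 um (10-16 sites)
      expect_true(all(tis@islets$radius * 2 >= 10 - 1e-9))
      expect_true(all(tis@islets$radius * 2 <= 16 + 1e-9))
      # achieved area fraction inside the class range, recounted brute force
      nBeta <- sum(tis@betaGrid > 0L)
      frac <- nBeta / (200 * 200)
      expect_equal(frac, tis@areaFraction, tolerance = 1 / 40000)
      expect_gte(frac, rng[1])
      expect_lte(frac, rng[2])
      expect_identical(nBeta, sum(tis@islets$nBeta))
    }
  }
})

test_that("membrane rings are exactly the non-islet sites adjacent to islet sites", {
  set.seed(11)
  tis <- generateTissue(simConfig())
  isIslet <- tis@betaGrid > 0L
  # brute-force dilation of the islet mask
  dil <- matrix(FALSE, 200, 200)
  for (sx in -1:1) for (sy in -1:1) {
    xs <- pmin(pmax(1:200 + sx, 1), 200)
    ys <- pmin(pmax(1:200 + sy, 1), 200)
    dil <- dil | isIslet[xs, ys]
  }
  expectedRing <- dil & !isIslet
  expect_identical(unname(tis@membraneIslet > 0L), unname(expectedRing))
  # every ring site initialised to full strength
  expect_true(all(tis@membraneGrid[expectedRing] == tis@membraneStrength))
  expect_true(all(is.na(tis@membraneGrid[!expectedRing])))
})

test_that("islets with their rings are pairwise separated", {
  set.seed(12)
  tis <- generateTissue(simConfig(isletDensityClass = "high"))
  owner <- pmax(tis@betaGrid, tis@membraneIslet)
  # every Moore neighbour of an owned site belongs to the same islet or none
  clash <- FALSE
  for (sx in -1:1) for (sy in -1:1) {
    if (sx == 0 && sy == 0) next
    a <- owner[2:199, 2:199]
    b <- owner[2:199 + sx, 2:199 + sy]
    clash <- clash || any(a != 0L & b != 0L & a != b)
  }
  expect_false(clash)
})

test_that("a zero density override yields an empty tissue", {
  set.seed(1)
  tis <- generateTissue(simConfig(densityRange = c(0, 0)))
  expect_identical(nIslets(tis), 0L)
  expect_identical(betaCount(tis), 0L)
})

test_that("an unattainable density target raises a placement error", {
  set.seed(1)
  cfg <- simConfig(gridWidth = 40L, gridHeight = 40L,
                   densityRange = c(0.5, 0.6))
  expect_error(generateTissue(cfg, maxAttempts = 200L), "placement failed")
})

test_that("the same seed reproduces the tissue layout bit for bit", {
  set.seed(77)
  a <- generateTissue(simConfig())
  set.seed(77)
  b <- generateTissue(simConfig())
  expect_identical(a@betaGrid, b@betaGrid)
  expect_identical(a@membraneGrid, b@membraneGrid)
  expect_identical(a@islets, b@islets)
})

test_that("initial T cells are placed off islets and membranes with the 2:1 split", {
  for (n in c(3L, 9L, 27L)) {
    set.seed(n)
    cfg <- simConfig(nInitialTcells = n)
    tis <- generateTissue(cfg)
    cells <- placeInitialTCells(cfg, tis)
    expect_identical(nrow(cells), as.integer(n))
    expect_identical(sum(cells$subset == "effector"), as.integer(round(n * 2 / 3)))
    expect_true(all(cells$age == 0))
    expect_true(all(cells$generation == 0L))
    expect_false(anyDuplicated(cells[, c("x", "y")]) > 0)
    # brute-force membership check against islet and membrane site sets
    for (i in seq_len(n)) {
      expect_identical(tis@betaGrid[cells$x[i], cells$y[i]], 0L)
      expect_identical(tis@membraneIslet[cells$x[i], cells$y[i]], 0L)
    }
  }
})

test_that("tissue exports are faithful", {
  set.seed(3)
  tis <- generateTissue(simConfig())
  f <- withr::local_tempfile(fileext = ".txt")
  writeTissueGrid(tis, f)
  lines <- readLines(f)
  expect_length(lines, 200)
  grid <- do.call(rbind, strsplit(lines, ""))
  expect_identical(sum(grid == "B"), betaCount(tis))
  expect_identical(sum(grid %in% c("m", "o")), sum(tis@membraneIslet > 0L))
  js <- jsonlite::fromJSON(isletManifest(tis))
  expect_equal(js$nIslets, nIslets(tis))
  expect_equal(js$areaFraction, tis@areaFraction)
  expect_equal(nrow(js$islets), nIslets(tis))
})
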