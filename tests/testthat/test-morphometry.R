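# Density map, mean density, fibrosis score, area fractions, quantifySection.

test_that("tile density arithmetic: mucus and background count as airspace", {
  # one 10x10 tile: 40 collagen, 20 mucus, 40 background, all inside section
  lab <- matrix(4L, 10, 10)          # background
  lab[1:4, ] <- 1L                   # 40 collagen
  lab[5:6, ] <- 2L                   # 20 mucus
  mk <- masksFromLabels(lab)
  sec <- sectionFromLogical(matrix(TRUE, 10, 10))
  dm <- densityMap(mk, sec, buildTileGrid(10, 10, 10))
  expect_equal(tileDensities(dm)[1, 1], 0.40)

  # fully stained tile
  mkFull <- masksFromLabels(matrix(3L, 10, 10))
  expect_equal(tileDensities(densityMap(mkFull, sec,
                                        buildTileGrid(10, 10, 10)))[1, 1], 1)
})

test_that("tiles below the coverage threshold are excluded", {
  lab <- matrix(4L, 10, 20)
  lab[, 1:10] <- 3L
  mk <- masksFromLabels(lab)
  sec <- sectionFromLogical(cbind(matrix(TRUE, 10, 12),
                                  matrix(FALSE, 10, 8)))
  dm <- densityMap(mk, sec, buildTileGrid(10, 20, 10), minTileCoverage = 0.5)
  expect_true(includedTiles(dm)[1, 1])
  expect_false(includedTiles(dm)[1, 2])   # 20% coverage < 50%
  expect_error(densityMap(mk, sectionFromLogical(matrix(FALSE, 10, 20) |
                                                   cbind(matrix(TRUE, 10, 2),
                                                         matrix(FALSE, 10, 18))),
                          buildTileGrid(10, 20, 10)),
               class = "fqEmptyMapError")
})

test_that("mean density and fibrosis score follow their definitions", {
  mkDmap <- function(d) {
    g <- buildTileGrid(length(d), 1, 1)
    new("DensityMap", density = matrix(d, ncol = 1),
        coverage = matrix(1, length(d), 1),
        sectionPx = matrix(1L, length(d), 1),
        included = matrix(TRUE, length(d), 1),
        tau = 0.75, minTileCoverage = 0.5, grid = g)
  }
  expect_equal(meanTissueDensity(mkDmap(rep(0.5, 4))), 0.5)
  expect_equal(meanTissueDensity(mkDmap(c(0, 1))), 0.5)
  set.seed(1); d <- runif(97)
  expect_equal(meanTissueDensity(mkDmap(d)), sum(d) / 97, tolerance = 1e-12)

  expect_equal(fibrosisScore(mkDmap(c(0.8, 0.9, 0.76, 0.5))), 75)
  expect_equal(fibrosisScore(mkDmap(rep(0.75, 5))), 0)  # strict >
  expect_equal(fibrosisScore(mkDmap(rep(0, 3))), 0)
})

test_that("area fractions are ratios to section area", {
  lab <- matrix(4L, 40, 40)
  lab[1:10, 1:40] <- 3L          # 400 parenchyma
  lab[11:15, 1:40] <- 1L         # 200 collagen
  mk <- masksFromLabels(lab)
  sec <- sectionFromLogical(rbind(matrix(TRUE, 25, 40),
                                  matrix(FALSE, 15, 40)))  # 1000 px section
  expect_equal(areaFraction(mk, "collagen_red", sec), 20)
  expect_equal(areaFraction(mk, "mucus_blue", sec), 0)
  expect_error(areaFraction(mk, "immunopositive_brown", sec),
               class = "fqValidationError")
})

test_that("density map and fractions equal an independent per-pixel recount", {
  for (seed in c(11, 23)) {
    gen <- generateSection(smallSpec(seed = seed, width = 240, height = 240,
                                     fibroticFocusFraction = 0.25))
    q <- quantifySection(gen$slide, smallConfig(), keepIntermediates = TRUE)
    oracle <- naiveDensityOracle(q$masks, q$section, q$dmap@grid)
    expect_identical(oracle$included, includedTiles(q$dmap))
    expect_equal(tileDensities(q$dmap), oracle$density, tolerance = 1e-14)
    expect_equal(meanTissueDensity(q$dmap),
                 mean(oracle$density[oracle$included]), tolerance = 1e-12)
    expect_equal(fibrosisScore(q$dmap),
                 100 * sum(oracle$density[oracle$included] > 0.75) /
                   sum(oracle$included), tolerance = 1e-12)
    expect_equal(q$result@collagenPct,
                 naiveAreaFraction(q$masks, "collagen_red", q$section),
                 tolerance = 1e-12)
  }
})

test_that("quantifySection is deterministic and reports context on failure", {
  gen <- generateSection(smallSpec(seed = 31, width = 200, height = 200))
  runs <- lapply(1:5, function(i) quantifySection(gen$slide, smallConfig()))
  for (i in 2:5) expect_identical(runs[[i]], runs[[1]])

  blank <- flatSlide(c(255, 255, 255), 60, 60)
  blank@slideId <- "blank_case"
  err <- tryCatch(quantifySection(blank, smallConfig()), error = identity)
  expect_s3_class(err, "fqEmptySectionError")
  expect_match(conditionMessage(err), "blank_case")
})

test_that("a slide generated without fibrotic foci scores zero fibrosis", {
  sp <- smallSpec(seed = 13, parenchymaFraction = 0.22,
                  collagenFraction = 0.05, mucusFraction = 0.01,
                  fibroticFocusFraction = 0)
  gen <- generateSection(sp)
  expect_equal(gen$truth$realizedFocusFraction, 0)
  r <- quantifySection(gen$slide, smallConfig(tileEdgePx = 56))
  expect_equal(r@fibrosisScorePct, 0)
})

test_that("metrics stay in range across generated slides", {
  for (seed in c(2, 8, 15)) {
    gen <- generateSection(smallSpec(seed = seed,
                                     fibroticFocusFraction = 0.1 * seed %% 0.7))
    r <- quantifySection(gen$slide, smallConfig())
    expect_true(r@meanTissueDensity >= 0 && r@meanTissueDensity <= 1)
    expect_true(r@fibrosisScorePct >= 0 && r@fibrosisScorePct <= 100)
    expect_true(r@collagenPct >= 0 && r@collagenPct + r@mucusPct <= 100)
    expect_equal(r@sectionAreaMm2,
                 r@sectionAreaPx * 1.8^2 / 1e6, tolerance = 1e-12)
  }
})

test_that("mucus removal from the denominator is available as a config switch", {
  gen <- generateSection(smallSpec(seed = 17, mucusFraction = 0.03))
  rIn <- quantifySection(gen$slide, smallConfig(mucusAsSection = TRUE))
  rOut <- quantifySection(gen$slide, smallConfig(mucusAsSection = FALSE))
  expect_lt(rOut@sectionAreaPx, rIn@sectionAreaPx)
  expect_gt(rOut@collagenPct, rIn@collagenPct)  # smaller denominator
})
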