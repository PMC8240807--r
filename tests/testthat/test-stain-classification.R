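# Pixel classification, section segmentation, lumen exclusion, mucus mask.

test_that("reference colors classify to their own class; white to background", {
  prof <- defaultStainProfile("PSR_AB")
  for (cl in c("collagen_red", "mucus_blue", "parenchyma_yellow")) {
    s <- flatSlide(prof@referenceRGB[cl, ])
    expect_true(all(classMask(classifyPixels(s), cl)), info = cl)
  }
  s <- flatSlide(c(255, 255, 255))
  expect_true(all(classMask(classifyPixels(s), "background_white")))
  # dark desaturated pixel passes no stain threshold -> background
  s2 <- flatSlide(c(40, 40, 40))
  expect_true(all(classMask(classifyPixels(s2), "background_white")))
})

test_that("profile/mode mismatch is a validation error", {
  s <- flatSlide(c(255, 255, 255), mode = "IHC_CD68")
  expect_error(classifyPixels(s, defaultStainProfile("PSR_AB")),
               class = "fqValidationError")
})

test_that("classes form an exhaustive, mutually exclusive partition", {
  gen <- generateSection(smallSpec(seed = 3))
  mk <- classifyPixels(gen$slide)
  expect_equal(sum(classCounts(mk)), prod(dim(gen$slide)))
  # label matrix representation makes exclusivity structural; check masks
  total <- Reduce(`+`, lapply(classNames(mk),
                              function(cl) classMask(mk, cl) * 1L))
  expect_true(all(total == 1L))
})

test_that("classification recovers the generator label map nearly pixel-exactly", {
  gen <- generateSection(smallSpec(seed = 14))
  mk <- classifyPixels(gen$slide)
  counted <- classCounts(mk)
  truthCounts <- setNames(
    tabulate(gen$truth$labels, length(gen$truth$classNames)),
    gen$truth$classNames)
  secArea <- sum(gen$truth$sectionRect)
  for (cl in names(counted))
    expect_lt(abs(counted[cl] - truthCounts[cl]), 0.005 * secArea)
})

test_that("classification is deterministic and translation-invariant", {
  gen <- generateSection(smallSpec(seed = 4, width = 120, height = 120))
  a <- classifyPixels(gen$slide)
  b <- classifyPixels(gen$slide)
  expect_identical(a@labels, b@labels)

  # embed the slide at an offset in a white canvas: labels shift identically
  px <- pixels(gen$slide)
  big <- array(255L, c(150, 150, 3))
  big[21:140, 31:150, ] <- px
  shifted <- SlideImage(big, micronsPerPixel = 1.8, stainMode = "PSR_AB")
  mkS <- classifyPixels(shifted)
  expect_identical(mkS@labels[21:140, 31:150], a@labels)
})

test_that("stain profile JSON round trip preserves classification", {
  prof <- defaultStainProfile("PSR_AB")
  f <- tempfile(fileext = ".json")
  writeStainProfile(prof, f)
  back <- readStainProfile(f)
  expect_equal(back@referenceRGB, prof@referenceRGB)
  expect_equal(back@thresholds[rownames(prof@referenceRGB)],
               prof@thresholds[rownames(prof@referenceRGB)])
  gen <- generateSection(smallSpec(seed = 2, width = 100, height = 100))
  expect_identical(classifyPixels(gen$slide, back)@labels,
                   classifyPixels(gen$slide, prof)@labels)
})

test_that("section mask: empty slide errors, solid tissue is counted exactly", {
  white <- flatSlide(c(255, 255, 255), 40, 40)
  expect_error(sectionMask(classifyPixels(white)),
               class = "fqEmptySectionError")

  # solid 100 x 100 parenchyma rectangle inset in white
  px <- array(255, c(200, 200, 3))
  ref <- defaultStainProfile("PSR_AB")@referenceRGB["parenchyma_yellow", ]
  for (ch in 1:3) px[51:150, 51:150, ch] <- ref[ch]
  s <- SlideImage(px, 0.452, stainMode = "PSR_AB")
  sec <- sectionMask(classifyPixels(s))
  expect_equal(sectionArea(sec), 10000L)

  # an isolated 10-px speck below minObjectAreaPx is removed
  px2 <- px
  for (ch in 1:3) px2[10, 10:19, ch] <- ref[ch]
  sec2 <- sectionMask(classifyPixels(SlideImage(px2, 0.452,
                                                stainMode = "PSR_AB")),
                      minObjectAreaPx = 100)
  expect_equal(sectionArea(sec2), 10000L)
})

test_that("large-lumen exclusion respects the >= area boundary and wall band", {
  # tissue frame 150x150 with a central 50x50 hole; mpp 2 -> hole = 0.01 mm2
  px <- array(255, c(170, 170, 3))
  ref <- defaultStainProfile("PSR_AB")@referenceRGB["parenchyma_yellow", ]
  for (ch in 1:3) px[11:160, 11:160, ch] <- ref[ch]
  for (ch in 1:3) px[61:110, 61:110, ch] <- 255
  s <- SlideImage(px, 2, stainMode = "PSR_AB")
  sec <- sectionMask(classifyPixels(s), closingRadiusPx = 0)
  expect_equal(sectionArea(sec), 150L * 150L)   # hole filled into footprint

  # no holes >= threshold -> unchanged
  secBig <- excludeLargeLumina(sec, minLumenAreaMm2 = 0.0101,
                               wallDilationUm = 0, micronsPerPixel = 2)
  expect_equal(sectionArea(secBig), 150L * 150L)
  expect_equal(sum(secBig@excludedLumina), 0L)

  # hole area exactly at threshold -> excluded (>= comparison), no wall
  secEq <- excludeLargeLumina(sec, minLumenAreaMm2 = 0.01,
                              wallDilationUm = 0, micronsPerPixel = 2)
  expect_equal(sum(secEq@excludedLumina), 2500L)
  expect_equal(sectionArea(secEq), 150L * 150L - 2500L)

  # wall band of 10 um = 5 px grows the exclusion beyond the hole
  secW <- excludeLargeLumina(sec, minLumenAreaMm2 = 0.01,
                             wallDilationUm = 10, micronsPerPixel = 2)
  expect_gt(sum(secW@excludedLumina), 2500L)
  expect_true(all(secW@excludedLumina[61:110, 61:110]))

  # section with no interior holes is returned unchanged
  pxS <- array(255, c(60, 60, 3))
  for (ch in 1:3) pxS[11:50, 11:50, ch] <- ref[ch]
  secS <- sectionMask(classifyPixels(SlideImage(pxS, 2,
                                                stainMode = "PSR_AB")))
  out <- excludeLargeLumina(secS, 0.001, 10, 2)
  expect_identical(out@section, secS@section)
})

test_that("synthetic airway exclusion matches the generator structure map", {
  sp <- smallSpec(seed = 5, width = 500, height = 500, nLargeLumina = 1,
                  lumenRadiusUm = c(140, 160))
  gen <- generateSection(sp)
  q <- quantifySection(gen$slide,
                       smallConfig(minLumenAreaMm2 = 0.05,
                                   wallDilationUm = 20),
                       keepIntermediates = TRUE)
  lum <- gen$truth$lumenMask
  expect_gt(sum(lum), 0)
  # every lumen pixel is excluded
  expect_true(all(q$section@excludedLumina[lum]))
  # excluded area = lumen + wall ring of ~20 um (disc discretization slack)
  wallPx <- round(20 / 1.8)
  rpx <- sqrt(sum(lum) / pi)
  expectedArea <- pi * (rpx + wallPx)^2
  expect_lt(abs(sum(q$section@excludedLumina) - expectedArea),
            0.03 * expectedArea)
  # alveolar-scale holes were not excluded
  expect_gt(sum(gen$truth$airspaceMask & q$section@section), 0)
})

test_that("mucus mask counts painted mucus and rejects IHC mode", {
  gen0 <- generateSection(smallSpec(seed = 6, mucusFraction = 0))
  expect_equal(sum(mucusMask(classifyPixels(gen0$slide))), 0)

  gen <- generateSection(smallSpec(seed = 6, mucusFraction = 0.02))
  truthMucus <- sum(gen$truth$labels ==
                      match("mucus_blue", gen$truth$classNames))
  expect_equal(sum(mucusMask(classifyPixels(gen$slide))), truthMucus)

  genI <- generateSection(smallSpec(seed = 6, stainMode = "IHC_CD68"))
  expect_error(mucusMask(classifyPixels(genI$slide)),
               class = "fqValidationError")
})
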