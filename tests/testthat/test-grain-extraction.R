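test_that("pixel-size calibration divides scale bar length by pixels", {
  expect_equal(calibratePixelSize(1000, 1000), 1.0)
  expect_equal(calibratePixelSize(500, 1000), 2.0)
  expect_equal(calibratePixelSize(87, 1000), 1000 / 87)  # 11.494 um/px
  expect_error(calibratePixelSize(0, 1000), "positive")
  expect_error(calibratePixelSize(100, -1), "positive")
})

test_that("binarization separates the grain phase", {
  two <- matrix(c(10, 200), 20, 20)
  bin <- binarizeImage(two, method = "otsu")
  expect_identical(bin, two == 200)

  fx <- matrix(c(50, 150), 10, 10)
  expect_identical(binarizeImage(fx, method = "fixed", threshold = 100),
                   fx == 150)

  expect_error(binarizeImage(matrix(1, 5, 5), method = "otsu"),
               "constant")

  # inversion flips which phase is foreground
  expect_identical(binarizeImage(two, method = "otsu", invert = TRUE),
                   two == 10)

  # on a noisy synthetic render, nearly all true grain pixels are kept
  r <- renderCrossSection(ImageSpec(512, 512, 10, referenceSiteSpec(),
    targetAreaFraction = 0.3, noiseSd = 0.02), seed = 31)
  bin <- binarizeImage(r$image, method = "otsu")
  truthFg <- r$truth@labelImage > 0
  expect_gt(mean(bin[truthFg]), 0.99)
})

test_that("median-filter chain removes specks and is idempotent on clean discs", {
  speck <- matrix(FALSE, 20, 20); speck[10, 10] <- TRUE
  expect_false(any(denoiseBinary(speck, steps = list("despeckle"))))

  disc <- mkDisc(70.5, 70.5, 50)
  expect_identical(denoiseBinary(disc), disc)

  # salt-and-pepper corruption (1% flips) is almost fully repaired
  set.seed(17)
  noisy <- xor(disc, matrix(runif(length(disc)) < 0.01, nrow(disc)))
  expect_gte(mean(denoiseBinary(noisy) == disc), 0.995)

  # empty image passes through
  expect_false(any(denoiseBinary(matrix(FALSE, 10, 10))))

  # hole filling restores leached cores
  ring <- disc & !mkDisc(70.5, 70.5, 20)
  expect_identical(denoiseBinary(ring, steps = list("fill_holes")), disc)
})

test_that("watershed separation splits touching grains", {
  two <- mkDisc(30.5, 30.5, 15, 60, 120) | mkDisc(30.5, 90.5, 15, 60, 120)
  expect_identical(max(separateTouching(two)), 2L)

  # figure-eight: two equal discs overlapping by 20% of the radius
  r <- 30
  fig8 <- mkDisc(40.5, 60.5, r, 80, 180) |
    mkDisc(40.5, 60.5 + 1.8 * r, r, 80, 180)
  lab <- separateTouching(fig8)
  expect_identical(max(lab), 2L)
  # the two labels are of comparable size (split along the neck)
  sizes <- tabulate(lab[lab > 0])
  expect_gt(min(sizes) / max(sizes), 0.8)

  # labels are consecutive and separated by background lines
  expect_identical(sort(unique(as.integer(lab))), 0:2)

  # dense touching pack: label count within +/-5% of ground truth
  pack <- renderCrossSection(ImageSpec(640, 640, 10, referenceSiteSpec(),
    targetAreaFraction = 0.42, noiseSd = 0), seed = 1)
  labP <- separateTouching(binarizeImage(pack$image, "fixed",
                                         threshold = 0.5))
  nTrue <- pack$truth@meta$nGrains
  expect_lt(abs(max(labP) - nTrue) / nTrue, 0.05)
})

test_that("Feret diameter equals geometry and the brute-force oracle", {
  # axis-aligned 10x10 px square at 1 um/px: diagonal 10*sqrt(2) px
  sq <- matrix(0L, 30, 30); sq[10:19, 10:19] <- 1L
  tab <- measureObjects(sq, 1)
  expect_equal(tab$feret_diameter_mm, 10 * sqrt(2) / 1000)

  # digitized disc of diameter 100 px at 10 um/px: Feret = 1.00 mm
  # within 1 px (the crack-boundary outline adds up to half a pixel per
  # side)
  dl <- matrix(0L, 140, 140); dl[mkDisc(70.5, 70.5, 49.5)] <- 1L
  tabD <- measureObjects(dl, 10)
  expect_lt(abs(tabD$feret_diameter_mm - 1.0), 10 / 1000)
  expect_gt(tabD$circularity, 0.85)

  # every object of a random binary scene matches the O(n^2) oracle
  # exactly (same corner-point set, same arithmetic)
  set.seed(23)
  lab <- separateTouching(matrix(runif(4900) > 0.45, 70, 70))
  tabR <- measureObjects(lab, 1)
  for (i in tabR$label) {
    bp <- boundaryPixelsOf(lab, i)
    expect_identical(feretDiameter(bp), bruteFeret(bp))
    expect_equal(tabR$feret_diameter_mm[i] * 1000, feretDiameter(bp),
                 tolerance = 1e-12)
  }

  # convex polygon fixture
  poly <- matrix(0L, 60, 60)
  for (r in 1:60) for (c in 1:60)
    if (r + c > 40 && r + c < 95 && c - r < 25 && r - c < 30) poly[r, c] <- 1L
  bpP <- boundaryPixelsOf(poly, 1L)
  expect_identical(feretDiameter(bpP), bruteFeret(bpP))

  expect_identical(nrow(measureObjects(matrix(0L, 10, 10), 1)), 0L)
})

test_that("measurement is deterministic", {
  r <- renderCrossSection(ImageSpec(256, 256, 10,
    referenceSiteSpec(nGrains = 10L), targetAreaFraction = 0.3), seed = 2)
  run <- function() {
    lab <- separateTouching(binarizeImage(r$image, "otsu"))
    measureObjects(lab, 10)
  }
  expect_identical(run(), run())
})

test_that("ooid selection excludes border objects and bioclasts", {
  # mid-sized circular objects all selected
  img <- matrix(0L, 200, 200)
  img[mkDisc(50.5, 50.5, 20, 200)] <- 1L
  img[mkDisc(140.5, 140.5, 25, 200)] <- 2L
  tab <- measureObjects(img, 10)
  g <- selectOoids(tab, siteId = "ok")
  expect_length(diameters(g), 2L)

  # border-touching disc excluded regardless of other criteria
  imgB <- img
  imgB[mkDisc(1, 100.5, 20, 200)] <- 3L
  tabB <- measureObjects(imgB, 10)
  expect_true(tabB$touches_border[3])
  gB <- selectOoids(tabB, siteId = "border")
  expect_length(diameters(gB), 2L)

  # rendered bioclasts (elongated) fail the circularity floor
  r <- renderCrossSection(ImageSpec(768, 768, 10, referenceSiteSpec(),
    targetAreaFraction = 0.2, nBioclasts = 20L, noiseSd = 0), seed = 41)
  lab <- separateTouching(binarizeImage(r$image, "fixed", threshold = 0.5))
  tabR <- measureObjects(lab, 10)
  gR <- selectOoids(tabR, minCircularity = 0.7, siteId = "bio")
  tabSel <- attr(gR, "objectTable")
  # no selected object overlaps the ground-truth bioclast mask
  sel <- tabSel$label[tabSel$selected]
  bioLabs <- unique(lab[r$truth@bioclastMask & lab > 0])
  expect_length(intersect(sel, bioLabs), 0L)

  # zero survivors is an instructive error
  expect_error(selectOoids(tab, minAreaMm2 = 10), "selection criteria")
})

test_that("end-to-end recovery matches ground truth on noise-free renders", {
  # 5 um/px keeps the half-pixel outline bias below 2% of the ~50 px
  # median grain, so the per-grain error budget is meaningful
  r <- renderCrossSection(ImageSpec(1024, 1024, 5, referenceSiteSpec(),
    targetAreaFraction = 0.18, noiseSd = 0), seed = 11)
  lab <- separateTouching(binarizeImage(r$image, "fixed", threshold = 0.5))
  tab <- measureObjects(lab, 5)
  g <- selectOoids(tab, siteId = "rec")

  # per-grain match via centroid lookup in the ground-truth label image
  truthLab <- r$truth@labelImage
  ctr <- cbind(round(tab$centroid_row), round(tab$centroid_col))
  trueId <- truthLab[ctr]
  ok <- trueId > 0
  relErr <- abs(tab$feret_diameter_mm[ok] -
                  r$truth@diametersMm[trueId[ok]]) /
    r$truth@diametersMm[trueId[ok]]
  expect_lt(median(relErr), 0.03)

  # distributional recovery
  H <- hellinger(estimateDensity(log(diameters(g))),
                 estimateDensity(log(r$truth@diametersMm)))
  expect_lt(H, 0.1)
})
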