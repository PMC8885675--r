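test_that("half-maximum-height threshold is the probe-median midpoint", {
  v <- array(100, c(20, 20, 20))
  v[8:12, 8:12, 8:12] <- 200
  expect_equal(hmhThreshold(v, c(10, 10, 10), c(3, 3, 3)), 150)
  # probe symmetry
  expect_equal(hmhThreshold(v, c(3, 3, 3), c(10, 10, 10)), 150)
  expect_error(hmhThreshold(v, c(3, 3, 3), c(17, 17, 17)), "equal")
  expect_error(hmhThreshold(v, c(0, 3, 3), c(10, 10, 10)), "outside")

  # noisy render: threshold within 5 gray levels (0-255 scale) of ideal
  inc <- data.frame(cx = 40, cy = 40, cz = 40, a_mm = 2, b_mm = 2,
                    c_mm = 2, rx = 0, ry = 0, rz = 0, intensity = 0.85)
  vs <- VolumeSpec(c(80, 80, 80), 50, inclusions = inc, noiseSd = 5 / 255)
  rv <- renderVolume(vs, seed = 51, poreFraction = 0)
  thr <- hmhThreshold(rv$volume, c(40, 40, 40), c(5, 5, 5))
  expect_lt(abs(thr - (0.85 + 0.35) / 2), 5 / 255)
})

test_that("segmentation labels each rendered inclusion once", {
  shp <- c(144, 144, 144)
  inc6 <- randomInclusions(6, shp, 60, seed = 52)
  rv <- renderVolume(VolumeSpec(shp, 60, inclusions = inc6,
                                noiseSd = 0.02), seed = 53)
  thr <- hmhThreshold(rv$volume,
                      objectProbe = round(unlist(inc6[1, c("cx", "cy",
                                                           "cz")])),
                      backgroundProbe = c(3, 3, 3))
  lab <- segmentInclusions(rv$volume, thr)
  expect_identical(max(lab), 6L)

  # threshold above the global maximum: zero labels, with a warning
  expect_warning(lab0 <- segmentInclusions(rv$volume, 2), "no inclusion")
  expect_identical(max(lab0), 0L)

  # two ellipsoids separated by one background voxel stay distinct
  v <- array(0, c(30, 30, 30))
  v[5:14, 5:14, 5:14] <- 1
  v[16:25, 5:14, 5:14] <- 1
  expect_identical(max(segmentInclusions(v, 0.5, minVolumeVox = 8)), 2L)
  # ... and merge when they touch (26-connectivity)
  v[15, 5:14, 5:14] <- 1
  expect_identical(max(segmentInclusions(v, 0.5, minVolumeVox = 8)), 1L)
})

test_that("moment-tensor axes recover rendered ellipsoid extents", {
  voxMm <- 50 / 1000
  # sphere of diameter 2 mm
  inc <- data.frame(cx = 40, cy = 40, cz = 40, a_mm = 2, b_mm = 2,
                    c_mm = 2, rx = 0, ry = 0, rz = 0, intensity = 0.85)
  rv <- renderVolume(VolumeSpec(c(80, 80, 80), 50, inclusions = inc),
                     seed = 54, poreFraction = 0)
  ax <- measureAxes(which(rv$truth@labelVolume == 1L, arr.ind = TRUE), 50)
  expect_true(all(abs(ax - 2) < voxMm))

  # axis-aligned ellipsoid (3, 2, 1) mm within one voxel per axis
  incE <- data.frame(cx = 48, cy = 48, cz = 48, a_mm = 3, b_mm = 2,
                     c_mm = 1, rx = 0, ry = 0, rz = 0, intensity = 0.85)
  rvE <- renderVolume(VolumeSpec(c(96, 96, 96), 50, inclusions = incE),
                      seed = 55, poreFraction = 0)
  axE <- measureAxes(which(rvE$truth@labelVolume == 1L, arr.ind = TRUE), 50)
  expect_true(all(abs(axE - c(3, 2, 1)) < voxMm))

  # rotated copies give the same sorted extents within 1.5 voxels
  for (ang in list(c(pi / 6, 0, 0), c(pi / 6, pi / 4, 0.3))) {
    incR <- transform(incE, rx = ang[1], ry = ang[2], rz = ang[3])
    rvR <- renderVolume(VolumeSpec(c(96, 96, 96), 50, inclusions = incR),
                        seed = 56, poreFraction = 0)
    axR <- measureAxes(which(rvR$truth@labelVolume == 1L,
                             arr.ind = TRUE), 50)
    expect_true(all(abs(axR - c(3, 2, 1)) < 1.5 * voxMm))
  }

  # translation invariance
  co <- which(rvE$truth@labelVolume == 1L, arr.ind = TRUE)
  expect_equal(measureAxes(co + 7L, 50), axE)

  # degenerate components are refused with a named degeneracy
  plane <- cbind(rep(1:5, 5), rep(1:5, each = 5), 1)
  expect_error(measureAxes(plane, 50), "coplanar")
  expect_error(measureAxes(cbind(1:9, 1, 1), 50), "collinear")
})

test_that("random ellipsoid suite stays within 1.5 voxels per axis", {
  voxMm <- 60 / 1000
  worst <- 0
  for (i in 1:20) {
    inc <- randomInclusions(1, c(80, 80, 80), 60,
                            axisRangeMm = c(1.8, 3.4), seed = 60 + i)
    rv <- renderVolume(VolumeSpec(c(80, 80, 80), 60, inclusions = inc),
                       seed = 90 + i, poreFraction = 0)
    ax <- measureAxes(which(rv$truth@labelVolume == 1L, arr.ind = TRUE), 60)
    tru <- sort(unlist(inc[1, c("a_mm", "b_mm", "c_mm")]),
                decreasing = TRUE)
    worst <- max(worst, max(abs(ax - tru)))
  }
  expect_lt(worst, 1.5 * voxMm)
})

test_that("inclusion means are compared to cavity means", {
  incTab <- data.frame(mean_diameter_mm = c(2.8, 2.7, 2.9))
  cavSame <- data.frame(mean_diameter_mm = c(2.8, 2.7, 2.9))
  expect_equal(compareInclusionsToCavities(incTab, cavSame)$difference_mm, 0)

  res <- compareInclusionsToCavities(
    data.frame(mean_diameter_mm = 3.0),
    data.frame(d1_mm = 1.9, d2_mm = 2.1))
  expect_equal(res$mean_inclusion_mm, 3.0)
  expect_equal(res$mean_cavity_mm, 2.0)
  expect_equal(res$difference_mm, 1.0)

  expect_error(compareInclusionsToCavities(incTab[0, , drop = FALSE],
                                           cavSame), "empty")
})
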