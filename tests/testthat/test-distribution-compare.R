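test_that("log transform is the natural logarithm with named errors", {
  expect_equal(logTransform(c(1.0)), 0)
  expect_equal(logTransform(exp(1)), 1)
  expect_equal(logTransform(c(0.25, 0.5)), log(c(0.25, 0.5)))
  expect_equal(round(logTransform(c(0.25, 0.5)), 4), c(-1.3863, -0.6931))
  expect_error(logTransform(c(0.2, -1, 0.3)), "record\\(s\\) 2")
})

test_that("bandwidth follows the robust Silverman rule exactly", {
  set.seed(2)
  x <- rnorm(1000)
  expect_identical(silvermanBandwidth(x),
                   0.9 * min(sd(x), IQR(x) / 1.34) * 1000^(-1 / 5))
  kde <- estimateDensity(x)
  expect_identical(bandwidth(kde), silvermanBandwidth(x))
  expect_error(estimateDensity(rep(1, 10)), "zero spread")
  expect_error(estimateDensity(1), "at least 2")
})

test_that("density estimates integrate to one and track the truth", {
  set.seed(3)
  for (n in c(50, 500, 5000)) {
    kde <- estimateDensity(rnorm(n))
    expect_lt(abs(oolite:::trapz(densityGrid(kde), densityValues(kde)) - 1),
              1e-6)
    expect_true(all(densityValues(kde) >= 0))
  }
  kde <- estimateDensity(rnorm(5000))
  expect_lt(max(abs(densityValues(kde) - dnorm(densityGrid(kde)))), 0.05)
})

test_that("Hellinger distance has the identical and disjoint limits", {
  set.seed(4)
  f <- estimateDensity(rnorm(300))
  expect_lt(hellinger(f, f), 1e-6)

  u1 <- new("DensityEstimate", grid = seq(0, 1, length.out = 257),
            density = rep(1, 257), bandwidth = 0.1, nSource = 10L)
  u2 <- new("DensityEstimate", grid = seq(2, 3, length.out = 257),
            density = rep(1, 257), bandwidth = 0.1, nSource = 10L)
  expect_identical(hellinger(u1, u2), 1)
  expect_identical(bhattacharyya(u1, u2), 0)
  expect_equal(bhattacharyya(u1, u1), 1)

  # symmetry of the quadrature
  set.seed(5)
  g <- estimateDensity(rnorm(300, 1))
  expect_identical(hellinger(f, g), hellinger(g, f))
})

test_that("KDE Hellinger matches the closed-form Gaussian oracle", {
  # paired design (x vs x + shift): sampling noise cancels, leaving only
  # the KDE smoothing bias, so the comparison isolates the quadrature
  set.seed(6)
  xa <- rnorm(5000)
  fa <- estimateDensity(xa)
  for (dmu in c(0, 0.5, 1, 2)) {
    fb <- estimateDensity(xa + dmu)
    expect_lt(abs(hellinger(fa, fb) - gaussianHellinger(0, 1, dmu, 1)),
              0.02)
  }
  # Bhattacharyya at dmu = 1: exp(-1/8)
  fb1 <- estimateDensity(xa + 1)
  expect_lt(abs(bhattacharyya(fa, fb1) - exp(-1 / 8)), 0.02)
})

test_that("doubling the grid density barely changes H", {
  set.seed(7)
  f <- estimateDensity(rnorm(800), nGrid = 2048L)
  g <- estimateDensity(rnorm(800, 0.6), nGrid = 2048L)
  expect_lt(abs(hellinger(f, g, nGrid = 2048L) -
                  hellinger(f, g, nGrid = 4096L)), 1e-4)
})

test_that("pairwise distances form a metric panel", {
  panel <- plantedPanel(seed = 100)
  D <- pairwiseDistances(panel)
  m <- distanceValues(D)
  expect_identical(diag(m), setNames(rep(0, 6), sampleLabels(D)))
  expect_identical(m, t(m))
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)

  # identical samples give (near) zero distance
  dup <- panel[1:2]
  dup[[2]] <- GrainSample("copy", diameters(panel[[1]]))
  expect_lt(distanceValues(pairwiseDistances(dup))[1, 2], 1e-6)

  # permutation of the input permutes the matrix without numeric change
  Dp <- pairwiseDistances(panel[c(3, 1, 2, 6, 5, 4)])
  mp <- distanceValues(Dp)
  expect_identical(mp[sampleLabels(D), sampleLabels(D)], m)

  expect_error(pairwiseDistances(list(panel[[1]], panel[[1]])),
               "duplicate")
})

test_that("pooled ranking recovers a planted provenance match", {
  panel <- plantedPanel(seed = 200)
  rk <- distanceToPooled(panel, c("ref-head", "ref-leg"))
  expect_identical(nrow(rk), 4L)            # members excluded from ranking
  expect_false(any(c("ref-head", "ref-leg") %in% rk$site))
  expect_identical(rk$site[1], "planted")
  expect_false(is.unsorted(rk$H))

  # pooling two identical samples leaves the pooled density unchanged at
  # fixed bandwidth (the n-dependent Silverman factor is held constant so
  # the comparison isolates the pooling itself)
  d1 <- diameters(panel[[1]])
  h <- silvermanBandwidth(log(d1))
  kdeOne <- estimateDensity(log(d1), bw = h)
  kdeTwin <- estimateDensity(log(c(d1, d1)), bw = h)
  probe <- estimateDensity(logTransform(panel[[4]]))
  expect_lt(abs(hellinger(kdeTwin, probe) - hellinger(kdeOne, probe)),
            1e-6)

  expect_error(distanceToPooled(panel, character(0)), "non-empty")
  expect_error(distanceToPooled(panel, "nope"), "not present")
})

test_that("sample summaries use the n-1 standard deviation", {
  s1 <- summarizeSample(GrainSample("a", c(1, 1, 1)))
  expect_equal(s1$mean_mm, 1); expect_equal(s1$sd_mm, 0)
  s2 <- summarizeSample(GrainSample("b", c(0.1, 0.3)))
  expect_equal(s2$mean_mm, 0.2)
  expect_equal(s2$sd_mm, sd(c(0.1, 0.3)))
  expect_equal(round(s2$sd_mm, 4), 0.1414)
  expect_identical(s2$n, 2L)
})

test_that("modality concordance detects CT size overestimation", {
  sp <- referenceSiteSpec(nGrains = 2000L)
  base <- sampleDiameters(sp, 300)

  # identical samples relabeled: H ~ 0, shift exactly 0
  ct <- GrainSample("s", diameters(base), modality = "CT")
  ts <- GrainSample("s", diameters(base), modality = "TS")
  mc <- modalityConcordance(ct, ts)
  expect_lt(mc$H, 1e-6)
  expect_identical(mc$meanLogShift, 0)

  # removing the smallest 10% raises the CT mean by construction
  d <- sort(diameters(base))
  ctTrunc <- GrainSample("s", d[-seq_len(200)], modality = "CT")
  expect_gt(modalityConcordance(ctTrunc, ts)$meanLogShift, 0)

  # two seeded draws of one site are closer than any between-site pair
  spTs <- referenceSiteSpec(nGrains = 2000L, modality = "TS")
  rep2 <- sampleDiameters(spTs, 301)
  within <- modalityConcordance(ct, rep2)$H
  panel <- plantedPanel(seed = 400)
  m <- distanceValues(pairwiseDistances(panel))
  distinct <- m[lower.tri(m)]
  # exclude the planted replicate pairs (same spec): columns 1:3 pairwise
  between <- m[4:6, 1:3]
  expect_lt(within, min(between))

  expect_error(modalityConcordance(ct, ctTrunc), "different modalities")
})
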