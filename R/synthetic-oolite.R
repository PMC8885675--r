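## Synthetic oolite generator: seeded grain-diameter samples, rendered 2D
## cross-sections and rendered 3D volumes with ground truth. All randomness
## is local to the call (one seeded generator per call, no global state).

#' Draw grain diameters from a site specification
#'
#' Samples `nGrains` diameters (mm) from the site's lognormal mixture. A
#' component with `logSd = 0` contributes a point mass at `exp(logMean)`.
#'
#' @param spec a [SiteSpec-class].
#' @param seed integer seed; fixed seed gives an identical sample.
#' @return A [GrainSample-class] carrying the draws and generation metadata.
#' @examples
#' s <- sampleDiameters(SiteSpec("a", 1, log(0.25), 0.4, 100), seed = 1)
#' mean(diameters(s))
#' @export
sampleDiameters <- function(spec, seed) {
  validObject(spec)
  d <- withLocalSeed(seed, {
    k <- sample.int(length(spec@weights), spec@nGrains, replace = TRUE,
                    prob = spec@weights)
    exp(rnorm(spec@nGrains, mean = spec@logMean[k], sd = spec@logSd[k]))
  })
  GrainSample(spec@siteId, d, modality = spec@modality,
              provenance = list(generator = "lognormal-mixture",
                                seed = as.integer(seed),
                                logMean = spec@logMean, logSd = spec@logSd,
                                weights = spec@weights))
}

#' Analytic mean diameter of a site's mixture
#'
#' The exact expectation of the lognormal mixture,
#' \eqn{\sum_k w_k \exp(\mu_k + \sigma_k^2/2)} (mm); used as the oracle for
#' render ground truth.
#'
#' @param spec a [SiteSpec-class].
#' @return numeric(1), mm.
#' @export
mixtureMeanMm <- function(spec) {
  sum(spec@weights * exp(spec@logMean + spec@logSd^2 / 2))
}

#' Analytic mixture density of log diameters
#'
#' Mixture-of-normals density on the log-mm scale, for convergence checks of
#' generated samples against their specification.
#'
#' @param spec a [SiteSpec-class].
#' @param x log-diameter values at which to evaluate.
#' @return numeric vector of density values.
#' @export
mixtureLogDensity <- function(spec, x) {
  rowSums(vapply(seq_along(spec@weights), function(k) {
    spec@weights[k] * stats::dnorm(x, spec@logMean[k], spec@logSd[k])
  }, numeric(length(x))))
}

#' Site specification matching the figurine's reported granulometry
#'
#' Single-lognormal site whose analytic mean and SD equal 0.253 mm and
#' 0.131 mm, the summary granulometry of the reference micro-CT sample
#' (moment-matched: \eqn{\sigma^2 = \log(1 + s^2/m^2)},
#' \eqn{\mu = \log m - \sigma^2/2}).
#'
#' @param siteId site label.
#' @param nGrains number of grains to draw.
#' @param modality `"CT"` or `"TS"`.
#' @return A [SiteSpec-class].
#' @export
referenceSiteSpec <- function(siteId = "venus", nGrains = 500L,
                              modality = "CT") {
  m <- 0.253; s <- 0.131
  sg2 <- log(1 + (s / m)^2)
  SiteSpec(siteId, weights = 1, logMean = log(m) - sg2 / 2,
           logSd = sqrt(sg2), nGrains = nGrains, modality = modality)
}

## Gray levels of the rendered phases (unit scale, bright = dense).
.render <- list(background = 0.22, cortex = 0.75, core = 0.08,
                bioclast = 0.88)

#' Render a synthetic oolite cross-section
#'
#' Places non-overlapping ellipses (mild eccentricity, touching allowed up
#' to 1 px) by rejection sampling until the target area fraction or the
#' placement budget (100 attempts per expected grain) is reached. Optional
#' features: leached (dark-core) ooids, elongated bright bioclasts excluded
#' from the ground-truth label mask, and `nLayers` horizontal crossbedding
#' bands whose mean grain size alternates. Additive Gaussian noise is
#' applied last. Bright = dense; use `invert = TRUE` in [binarizeImage()]
#' for thin-section contrast.
#'
#' @param spec an [ImageSpec-class].
#' @param seed integer seed.
#' @return list with elements `image` ([GrayImage-class]) and `truth`
#'   ([GroundTruth-class]); `truth@meta$achievedAreaFraction` reports the
#'   packing actually reached (a warning is raised if it falls short of
#'   the target).
#' @export
renderCrossSection <- function(spec, seed) {
  validObject(spec)
  res <- withLocalSeed(seed, .renderCrossSectionImpl(spec))
  if (res$truth@meta$achievedAreaFraction <
      0.98 * spec@targetAreaFraction)
    warning(sprintf(
      "placement budget exhausted: achieved area fraction %.3f < target %.3f",
      res$truth@meta$achievedAreaFraction, spec@targetAreaFraction))
  res
}

.renderCrossSectionImpl <- function(spec) {
  h <- spec@heightPx; w <- spec@widthPx
  img <- matrix(.render$background, h, w)
  lab <- matrix(0L, h, w)
  bio <- matrix(FALSE, h, w)
  pxMm <- spec@pixelSizeUm / 1000     # mm per pixel

  meanDiamPx <- mixtureMeanMm(spec@site) / pxMm
  targetArea <- spec@targetAreaFraction * h * w
  expectGrains <- max(1, ceiling(targetArea / (pi * (meanDiamPx / 2)^2)))
  budget <- 100L * expectGrains

  layerMult <- function(cy) {
    if (spec@nLayers < 1L) return(1)
    band <- pmin(spec@nLayers, 1L + floor((cy - 1) / (h / spec@nLayers)))
    ifelse(band %% 2L == 0L, 1.18, 0.85)   # alternating sorting bands
  }

  placed <- matrix(numeric(0), ncol = 3)  # cy, cx, bounding radius (px)
  grains <- list()
  areaCovered <- 0
  attempts <- 0L
  while (areaCovered < targetArea && attempts < budget) {
    # draw the grain once, then search for a position: retrying positions
    # for the same grain keeps the rendered size distribution unbiased
    # (redrawing on failure would under-represent large grains)
    dMm0 <- exp(rnorm(1,
                      spec@site@logMean[kk <- sample.int(
                        length(spec@site@weights), 1,
                        prob = spec@site@weights)],
                      spec@site@logSd[kk]))
    ecc <- runif(1, 1, spec@eccentricityMax)
    theta <- runif(1, 0, pi)
    for (try in seq_len(200L)) {
      attempts <- attempts + 1L
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      dMm <- dMm0 * layerMult(cy)
      a <- dMm / pxMm / 2                # semi-major axis, px
      if (a < 1) break                   # sub-pixel grain: unrenderable
      b <- a / ecc
      # keep fully interior (border-touching grains are excluded
      # downstream anyway); forbid overlap of bounding circles beyond 1 px
      ok <- cy - a >= 2 && cy + a <= h - 1 && cx - a >= 2 && cx + a <= w - 1
      if (ok && nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
        ok <- all(dd >= placed[, 3] + a - 1)
      }
      if (ok) {
        placed <- rbind(placed, c(cy, cx, a))
        grains[[length(grains) + 1L]] <-
          list(cy = cy, cx = cx, a = a, b = b, theta = theta,
               dMm = 2 * a * pxMm)
        areaCovered <- areaCovered + pi * a * b
        break
      }
      if (attempts >= budget) break
    }
  }

  nG <- length(grains)
  hollow <- if (nG > 0) runif(nG) < spec@hollowFraction else logical(0)
  diamsMm <- numeric(nG)
  for (i in seq_len(nG)) {
    g <- grains[[i]]
    diamsMm[i] <- g$dMm
    m <- .ellipseMask(h, w, g$cy, g$cx, g$a, g$b, g$theta)
    img[m$idx] <- .render$cortex
    lab[m$idx] <- i
    if (hollow[i]) {
      core <- .ellipseMask(h, w, g$cy, g$cx, 0.45 * g$a, 0.45 * g$b, g$theta)
      img[core$idx] <- .render$core
    }
  }

  # bioclasts: elongated bright fragments, not part of the grain labels
  nPlacedBio <- 0L
  bioAttempts <- 0L
  while (nPlacedBio < spec@nBioclasts && bioAttempts < 200L * spec@nBioclasts) {
    bioAttempts <- bioAttempts + 1L
    a <- runif(1, 1.2, 2.2) * meanDiamPx / 2 * 2   # long semi-axis
    b <- a / runif(1, 4, 6)
    theta <- runif(1, 0, pi)
    cy <- runif(1, a + 2, h - a - 1); cx <- runif(1, a + 2, w - a - 1)
    if (nrow(placed) > 0) {
      dd <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
      if (any(dd < placed[, 3] + a - 1)) next
    }
    placed <- rbind(placed, c(cy, cx, a))
    m <- .ellipseMask(h, w, cy, cx, a, b, theta)
    img[m$idx] <- .render$bioclast
    bio[m$idx] <- TRUE
    nPlacedBio <- nPlacedBio + 1L
  }

  if (spec@noiseSd > 0) {
    img <- img + matrix(rnorm(h * w, sd = spec@noiseSd), h, w)
    img[img < 0] <- 0; img[img > 1] <- 1
  }

  truth <- new("GroundTruth", diametersMm = diamsMm, labelImage = lab,
               bioclastMask = bio, labelVolume = array(0L, c(1, 1, 1)),
               axesMm = data.frame(),
               meta = list(achievedAreaFraction = areaCovered / (h * w),
                           attempts = attempts, nGrains = nG,
                           nBioclasts = nPlacedBio))
  list(image = GrayImage(img, spec@pixelSizeUm), truth = truth)
}

## Pixel-center membership of a rotated ellipse; returns linear indices.
.ellipseMask <- function(h, w, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy; dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  inside <- u^2 + v^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  list(idx = cbind(rows[idx[, 1]], cols[idx[, 2]]))
}

#' Render a synthetic micro-CT volume
#'
#' Rasterizes rotated dense ellipsoids (the inclusions) over a porous rock
#' matrix; a fraction of matrix voxels are rendered as pores at background
#' intensity, and Gaussian noise is added last. Ground truth records the
#' label volume and each inclusion's true full axis lengths (mm, sorted
#' descending).
#'
#' @param spec a [VolumeSpec-class]; every inclusion must lie fully inside
#'   the volume.
#' @param seed integer seed.
#' @param poreFraction fraction of matrix voxels rendered as pores.
#' @return list with elements `volume` ([GrayVolume-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
renderVolume <- function(spec, seed, poreFraction = 0.12) {
  validObject(spec)
  inc <- spec@inclusions
  dims <- spec@shapeVox
  if (nrow(inc) > 0) {
    semiVox <- (cbind(inc$a_mm, inc$b_mm, inc$c_mm) / 2) *
      1000 / spec@voxelSizeUm
    rmax <- apply(semiVox, 1, max)
    ok <- inc$cx - rmax >= 1 & inc$cx + rmax <= dims[1] &
      inc$cy - rmax >= 1 & inc$cy + rmax <= dims[2] &
      inc$cz - rmax >= 1 & inc$cz + rmax <= dims[3]
    if (!all(ok))
      stop("inclusion(s) ", paste(which(!ok), collapse = ", "),
           " extend outside the volume")
  }
  withLocalSeed(seed, {
    vol <- array(spec@matrixIntensity, dims)
    if (poreFraction > 0) {
      pores <- runif(length(vol)) < poreFraction
      vol[pores] <- spec@backgroundIntensity
    }
    labv <- array(0L, dims)
    axes <- data.frame()
    for (i in seq_len(nrow(inc))) {
      R <- eulerRotation(inc$rx[i], inc$ry[i], inc$rz[i])
      semi <- c(inc$a_mm[i], inc$b_mm[i], inc$c_mm[i]) / 2 *
        1000 / spec@voxelSizeUm
      ctr <- c(inc$cx[i], inc$cy[i], inc$cz[i])
      rmax <- max(semi)
      xr <- max(1, floor(ctr[1] - rmax)):min(dims[1], ceiling(ctr[1] + rmax))
      yr <- max(1, floor(ctr[2] - rmax)):min(dims[2], ceiling(ctr[2] + rmax))
      zr <- max(1, floor(ctr[3] - rmax)):min(dims[3], ceiling(ctr[3] + rmax))
      gg <- expand.grid(x = xr, y = yr, z = zr)
      p <- t(t(as.matrix(gg)) - ctr)
      q <- p %*% R            # into the ellipsoid frame
      inside <- (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
        (q[, 3] / semi[3])^2 <= 1
      sel <- as.matrix(gg[inside, , drop = FALSE])
      vol[sel] <- inc$intensity[i]
      labv[sel] <- i
      axes <- rbind(axes, setNames(as.data.frame(t(sort(
        c(inc$a_mm[i], inc$b_mm[i], inc$c_mm[i]), decreasing = TRUE))),
        c("a_mm", "b_mm", "c_mm")))
    }
    if (spec@noiseSd > 0) {
      vol <- vol + array(rnorm(length(vol), sd = spec@noiseSd), dims)
      vol[vol < 0] <- 0; vol[vol > 1] <- 1
    }
    truth <- new("GroundTruth", diametersMm = numeric(0),
                 labelImage = matrix(0L, 1, 1),
                 bioclastMask = matrix(FALSE, 1, 1),
                 labelVolume = labv, axesMm = axes,
                 meta = list(nInclusions = nrow(inc)))
    list(volume = GrayVolume(vol, spec@voxelSizeUm), truth = truth)
  })
}

#' Random inclusion set for a volume specification
#'
#' Draws `n` non-overlapping ellipsoidal inclusions with random orientations
#' and axis lengths, for building [VolumeSpec-class] fixtures.
#'
#' @param n number of inclusions.
#' @param shapeVox volume dimensions (voxels).
#' @param voxelSizeUm micrometers per voxel.
#' @param axisRangeMm range of full axis lengths to draw from (mm).
#' @param intensity inclusion gray level.
#' @param seed integer seed.
#' @return data.frame suitable for the `inclusions` slot of a `VolumeSpec`.
#' @export
randomInclusions <- function(n, shapeVox, voxelSizeUm,
                             axisRangeMm = c(2.0, 3.4), intensity = 0.85,
                             seed = 1) {
  withLocalSeed(seed, {
    out <- data.frame()
    placed <- matrix(numeric(0), ncol = 4)  # cx cy cz rmax(vox)
    tries <- 0L
    while (nrow(out) < n && tries < 500L * n) {
      tries <- tries + 1L
      ax <- sort(runif(3, axisRangeMm[1], axisRangeMm[2]), decreasing = TRUE)
      rmax <- ax[1] / 2 * 1000 / voxelSizeUm
      ctr <- runif(3, rmax + 2, shapeVox - rmax - 1)
      if (any(ctr - rmax < 1) || any(ctr + rmax > shapeVox)) next
      if (nrow(placed) > 0) {
        dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - ctr)^2))
        if (any(dd < placed[, 4] + rmax + 3)) next   # >= 2 voxel separation
      }
      placed <- rbind(placed, c(ctr, rmax))
      out <- rbind(out, data.frame(
        cx = ctr[1], cy = ctr[2], cz = ctr[3],
        a_mm = ax[1], b_mm = ax[2], c_mm = ax[3],
        rx = runif(1, 0, pi), ry = runif(1, 0, pi), rz = runif(1, 0, pi),
        intensity = intensity))
    }
    if (nrow(out) < n)
      stop("could not place ", n, " non-overlapping inclusions")
    out
  })
}
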