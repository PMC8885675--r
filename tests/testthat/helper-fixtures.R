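## Shared fixtures and independent oracles.

## Solid disc mask; half-integer centers give discretizations without
## single-pixel protrusions.
mkDisc <- function(cy, cx, rad, nrow. = 140, ncol. = nrow.) {
  rr <- matrix(seq_len(nrow.), nrow., ncol.)
  cc <- matrix(seq_len(ncol.), nrow., ncol., byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= rad^2
}

## Brute-force Feret oracle: O(n^2) max pairwise distance over the corner
## points of the boundary pixels (independent of the hull-based path).
bruteFeret <- function(boundaryPx) {
  r <- boundaryPx[, 1]; c <- boundaryPx[, 2]
  pts <- unique(cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
                      c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)))
  max(stats::dist(pts))
}

boundaryPixelsOf <- function(lab, id) {
  bnd <- oolite:::.boundaryMask(lab)
  pos <- which(bnd, arr.ind = TRUE)
  pos[lab[pos] == id, , drop = FALSE]
}

## Closed-form Hellinger distance between two normal densities.
gaussianHellinger <- function(mu1, sd1, mu2, sd2) {
  bc <- sqrt(2 * sd1 * sd2 / (sd1^2 + sd2^2)) *
    exp(-(mu1 - mu2)^2 / (4 * (sd1^2 + sd2^2)))
  sqrt(1 - bc)
}

## RMS residual after optimal rigid (rotation/reflection + translation)
## alignment of configuration Y onto X, via SVD Procrustes.
procrustesRMS <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(mean((Yc %*% R - Xc)^2))
}

## Well-separated six-site panel with a planted match to the pooled pair.
plantedPanel <- function(seed, nGrains = 400L) {
  specs <- list(
    SiteSpec("ref-head", 1, -1.49, 0.45, nGrains),
    SiteSpec("ref-leg", 1, -1.49, 0.45, nGrains),
    SiteSpec("planted", 1, -1.49, 0.45, nGrains),
    SiteSpec("coarse", 1, -0.55, 0.35, nGrains),
    SiteSpec("fine", 1, -2.45, 0.35, nGrains),
    SiteSpec("verycoarse", 1, -0.05, 0.40, nGrains))
  lapply(seq_along(specs), function(i)
    sampleDiameters(specs[[i]], seed = seed + 1000L * i))
}
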