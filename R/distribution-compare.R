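## Statistical core: natural-log transform, Gaussian KDE with the robust
## Silverman bandwidth, Hellinger distance H^2(f_i, f_j) = 1 - int
## sqrt(f_i f_j) dx between per-site densities of log diameter, the
## Bhattacharyya coefficient 1 - H^2, pooled-sample ranking, summary
## statistics, and micro-CT vs thin-section concordance.

#' Natural-log transform of grain diameters
#'
#' @param sample a [GrainSample-class] or numeric vector of diameters (mm).
#' @return numeric vector of log diameters (log-mm offsets).
#' @export
logTransform <- function(sample) {
  d <- if (is(sample, "GrainSample")) diameters(sample) else sample
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad))
    stop("non-positive diameter at record(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  log(d)
}

#' Robust Silverman rule-of-thumb bandwidth
#'
#' \eqn{h = 0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}} (the robust
#' rule-of-thumb variant).
#'
#' @param x numeric sample.
#' @return bandwidth in the units of `x`.
#' @export
silvermanBandwidth <- function(x) {
  n <- length(x)
  if (n < 2L) stop("bandwidth requires at least 2 observations")
  s <- min(sd(x), IQR(x) / 1.34)
  if (s <= 0) s <- sd(x)           # pathological IQR = 0 with spread
  if (s <= 0) stop("bandwidth undefined: sample has zero spread")
  0.9 * s * n^(-1 / 5)
}

#' Kernel density estimate of log diameters
#'
#' Gaussian kernels with the [silvermanBandwidth()] unless overridden; the
#' density is evaluated on `nGrid` points spanning the sample range padded
#' by `pad` bandwidths and renormalized to unit trapezoidal integral.
#'
#' @param logValues numeric vector (log-mm), n >= 2 with nonzero spread.
#' @param nGrid number of grid points.
#' @param pad padding of the evaluation range, in bandwidths.
#' @param bw optional bandwidth override.
#' @return A [DensityEstimate-class].
#' @export
estimateDensity <- function(logValues, nGrid = 2048L, pad = 4, bw = NULL) {
  if (length(logValues) < 2L)
    stop("density estimation requires at least 2 observations")
  if (is.null(bw)) bw <- silvermanBandwidth(logValues)
  d <- stats::density(logValues, bw = bw, kernel = "gaussian",
                      from = min(logValues) - pad * bw,
                      to = max(logValues) + pad * bw, n = nGrid)
  y <- d$y / trapz(d$x, d$y)
  new("DensityEstimate", grid = d$x, density = y, bandwidth = bw,
      nSource = length(logValues))
}

## Evaluate two DensityEstimates on a shared grid spanning both supports
## (zero outside each original grid), renormalized so that identity of
## indiscernibles holds to round-off rather than to quadrature error.
.commonGrid <- function(f, g, nGrid = 2048L) {
  if (length(f@grid) == length(g@grid) &&
      isTRUE(all.equal(f@grid, g@grid, tolerance = 0))) {
    return(list(x = f@grid, fy = f@density, gy = g@density))
  }
  x <- seq(min(f@grid[1], g@grid[1]),
           max(f@grid[length(f@grid)], g@grid[length(g@grid)]),
           length.out = nGrid)
  ev <- function(d) {
    y <- approx(d@grid, d@density, xout = x, yleft = 0, yright = 0)$y
    y[y < 0] <- 0
    tot <- trapz(x, y)
    if (tot > 0) y / tot else y
  }
  list(x = x, fy = ev(f), gy = ev(g))
}

#' Hellinger distance between two density estimates
#'
#' \eqn{H = \sqrt{1 - \int \sqrt{f_i(x) f_j(x)}\, dx}} by trapezoidal
#' quadrature on a common evaluation grid; 0 for identical distributions,
#' 1 for distributions with no overlap. The result is clamped into
#' `[0, 1]` to absorb negative round-off under the square root.
#'
#' @param f,g [DensityEstimate-class] objects.
#' @param nGrid resolution of the common grid when the grids differ.
#' @return numeric(1) in `[0, 1]`.
#' @export
hellinger <- function(f, g, nGrid = 2048L) {
  cg <- .commonGrid(f, g, nGrid)
  bc <- trapz(cg$x, sqrt(cg$fy * cg$gy))
  sqrt(min(1, max(0, 1 - bc)))
}

#' Bhattacharyya coefficient
#'
#' \eqn{1 - H^2}: the overlap (mean root likelihood) of two distributions;
#' 1 for identical, 0 for disjoint distributions.
#'
#' @inheritParams hellinger
#' @return numeric(1) in `[0, 1]`.
#' @export
bhattacharyya <- function(f, g, nGrid = 2048L) {
  1 - hellinger(f, g, nGrid)^2
}

## One KDE per sample, on the log scale.
.panelDensities <- function(samples, nGrid = 2048L) {
  lapply(samples, function(s) estimateDensity(logTransform(s),
                                              nGrid = nGrid))
}

#' Pairwise Hellinger distances between grain samples
#'
#' Fits one log-diameter KDE per sample and computes the full symmetric
#' matrix of Hellinger distances.
#'
#' @param samples list of [GrainSample-class] objects with unique site ids.
#' @param nGrid KDE / quadrature grid resolution.
#' @return A [HellingerMatrix-class].
#' @export
pairwiseDistances <- function(samples, nGrid = 2048L) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  labels <- vapply(samples, siteId, "")
  if (anyDuplicated(labels))
    stop("duplicate site ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dens <- .panelDensities(samples, nGrid)
  n <- length(samples)
  H <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    H[i, j] <- H[j, i] <- hellinger(dens[[i]], dens[[j]], nGrid)
  }
  new("HellingerMatrix", labels = labels, values = H)
}

#' Rank sites by Hellinger distance to a pooled reference sample
#'
#' Concatenates the raw diameters of the pooled group (e.g. all head and
#' leg samples of a figurine), fits a single KDE, and returns every
#' non-member site with its distance to that pooled density, sorted
#' ascending (best match first).
#'
#' @param samples list of [GrainSample-class] objects.
#' @param pooledGroup character vector of site ids to pool; all must be
#'   present among `samples`.
#' @param nGrid KDE / quadrature grid resolution.
#' @return data.frame with columns `site` and `H`, ascending in `H`.
#' @export
distanceToPooled <- function(samples, pooledGroup, nGrid = 2048L) {
  if (length(pooledGroup) < 1L) stop("pooledGroup must be non-empty")
  labels <- vapply(samples, siteId, "")
  missing <- setdiff(pooledGroup, labels)
  if (length(missing))
    stop("pooled sites not present: ", paste(missing, collapse = ", "))
  pooledD <- unlist(lapply(samples[labels %in% pooledGroup], diameters))
  pooledKde <- estimateDensity(log(pooledD), nGrid = nGrid)
  others <- samples[!labels %in% pooledGroup]
  if (!length(others))
    stop("no sites outside the pooled group to rank")
  H <- vapply(others, function(s) {
    hellinger(estimateDensity(logTransform(s), nGrid = nGrid), pooledKde,
              nGrid)
  }, 0)
  out <- data.frame(site = vapply(others, siteId, ""), H = H)
  out[order(out$H, out$site), , drop = FALSE]
}

#' Summary statistics of a grain sample
#'
#' @param sample a [GrainSample-class].
#' @return one-row data.frame: `mean_mm`, `sd_mm` (n-1 denominator),
#'   `min_mm`, `max_mm`, `n`.
#' @export
summarizeSample <- function(sample) {
  d <- diameters(sample)
  if (!length(d)) stop("empty sample")
  data.frame(mean_mm = mean(d), sd_mm = if (length(d) > 1) sd(d) else 0,
             min_mm = min(d), max_mm = max(d), n = length(d))
}

#' Micro-CT vs thin-section concordance for one site
#'
#' Quantifies modality agreement as the Hellinger distance between the two
#' modality KDEs and the shift of mean log diameter (CT minus TS; positive
#' when micro-CT overestimates grain size, as it does when the smallest
#' ooid sections are overlooked).
#'
#' @param sampleCt,sampleTs [GrainSample-class] objects of the same nominal
#'   site with modalities `"CT"` and `"TS"`.
#' @param nGrid KDE / quadrature grid resolution.
#' @return list with elements `H` and `meanLogShift`.
#' @export
modalityConcordance <- function(sampleCt, sampleTs, nGrid = 2048L) {
  if (modality(sampleCt) == modality(sampleTs))
    stop("samples must come from different modalities (got two '",
         modality(sampleCt), "')")
  lct <- logTransform(sampleCt)
  lts <- logTransform(sampleTs)
  H <- hellinger(estimateDensity(lct, nGrid = nGrid),
                 estimateDensity(lts, nGrid = nGrid), nGrid)
  list(H = H, meanLogShift = mean(lct) - mean(lts))
}
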