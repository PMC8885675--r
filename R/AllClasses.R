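#' @import methods
#' @importFrom stats approx cor density dist median quantile rlnorm rnorm
#'   runif sd setNames IQR prcomp
#' @importFrom utils read.csv write.csv head
#' @useDynLib oolite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Specification classes for the synthetic-oolite generator
## ---------------------------------------------------------------------------

#' Per-site grain-size distribution specification
#'
#' Describes the grain-diameter distribution of one sampling site as a finite
#' mixture of lognormal components on the mm scale, together with the number
#' of grains to draw and the imaging modality the sample emulates.
#'
#' @slot siteId character(1), site label (unique within a panel).
#' @slot weights numeric, mixture weights; must sum to 1.
#' @slot logMean numeric, component means of log-diameter (log-mm).
#' @slot logSd numeric, component standard deviations of log-diameter (> 0,
#'   except that 0 is allowed to express a degenerate point mass).
#' @slot nGrains integer(1), number of grains to draw (>= 1).
#' @slot modality character(1), `"CT"` (micro-CT cross-section) or `"TS"`
#'   (petrographic thin section).
#'
#' @seealso [SiteSpec()], [sampleDiameters()]
#' @export
setClass("SiteSpec",
  representation(
    siteId = "character",
    weights = "numeric",
    logMean = "numeric",
    logSd = "numeric",
    nGrains = "integer",
    modality = "character"
  )
)

setValidity("SiteSpec", function(object) {
  msg <- character()
  if (length(object@siteId) != 1L || !nzchar(object@siteId))
    msg <- c(msg, "siteId must be a single non-empty string")
  k <- length(object@weights)
  if (k < 1L)
    msg <- c(msg, "at least one mixture component is required")
  if (length(object@logMean) != k || length(object@logSd) != k)
    msg <- c(msg, "weights, logMean and logSd must have equal length")
  if (any(object@weights < 0))
    msg <- c(msg, "mixture weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1 (within 1e-9)")
  if (any(object@logSd < 0))
    msg <- c(msg, "logSd must be >= 0")
  if (length(object@nGrains) != 1L || is.na(object@nGrains) ||
      object@nGrains < 1L)
    msg <- c(msg, "nGrains must be a single integer >= 1")
  if (!object@modality %in% c("CT", "TS"))
    msg <- c(msg, "modality must be 'CT' or 'TS'")
  if (length(msg)) msg else TRUE
})

#' Construct a [SiteSpec-class]
#'
#' @param siteId site label.
#' @param weights mixture weights (recycled to sum handled by validity; pass
#'   fractions summing to 1).
#' @param logMean,logSd per-component log-diameter mean and SD (log-mm).
#' @param nGrains number of grains to draw.
#' @param modality `"CT"` or `"TS"`.
#' @return A validated `SiteSpec`.
#' @examples
#' SiteSpec("venus-like", weights = c(0.6, 0.4),
#'          logMean = log(c(0.20, 0.35)), logSd = c(0.30, 0.25),
#'          nGrains = 500)
#' @export
SiteSpec <- function(siteId, weights = 1, logMean, logSd, nGrains,
                     modality = c("CT", "TS")) {
  modality <- match.arg(modality)
  new("SiteSpec", siteId = as.character(siteId),
      weights = as.numeric(weights), logMean = as.numeric(logMean),
      logSd = as.numeric(logSd), nGrains = as.integer(nGrains),
      modality = modality)
}

#' Synthetic cross-section rendering specification
#'
#' Parameters for rendering a 2D grayscale oolite cross-section: ooid packing
#' density, hollow (oomouldic) fraction, elongated bioclast contaminants,
#' alternating grain-size layering (crossbedding), and additive noise.
#' Intensities are on the unit gray scale `[0, 1]`, bright = dense
#' (attenuation convention); thin-section contrast is obtained by the
#' `invert` flag at binarization time.
#'
#' @slot widthPx,heightPx image size in pixels.
#' @slot pixelSizeUm pixel size in micrometers per pixel.
#' @slot targetAreaFraction fraction of the image area to cover with ooids
#'   (in (0, 0.9)).
#' @slot site a [SiteSpec-class] providing the diameter distribution.
#' @slot hollowFraction fraction of ooids rendered with a leached dark core.
#' @slot nBioclasts number of elongated bright bioclast contaminants.
#' @slot nLayers number of horizontal crossbedding bands with alternating
#'   mean-size multipliers (0 disables layering).
#' @slot noiseSd additive Gaussian noise SD in gray units.
#' @slot eccentricityMax maximal axis ratio of the rendered ellipses (>= 1).
#' @export
setClass("ImageSpec",
  representation(
    widthPx = "integer", heightPx = "integer", pixelSizeUm = "numeric",
    targetAreaFraction = "numeric", site = "SiteSpec",
    hollowFraction = "numeric", nBioclasts = "integer", nLayers = "integer",
    noiseSd = "numeric", eccentricityMax = "numeric"
  )
)

setValidity("ImageSpec", function(object) {
  msg <- character()
  if (object@widthPx < 8L || object@heightPx < 8L)
    msg <- c(msg, "image must be at least 8x8 pixels")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@targetAreaFraction <= 0 || object@targetAreaFraction >= 0.9)
    msg <- c(msg, "targetAreaFraction must lie in (0, 0.9)")
  if (object@hollowFraction < 0 || object@hollowFraction > 1)
    msg <- c(msg, "hollowFraction must lie in [0, 1]")
  if (object@nBioclasts < 0L) msg <- c(msg, "nBioclasts must be >= 0")
  if (object@nLayers < 0L) msg <- c(msg, "nLayers must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@eccentricityMax < 1 || object@eccentricityMax > 1.3)
    msg <- c(msg, "eccentricityMax must lie in [1, 1.3]")
  if (length(msg)) msg else TRUE
})

#' Construct an [ImageSpec-class]
#'
#' @param widthPx,heightPx image size in pixels.
#' @param pixelSizeUm micrometers per pixel.
#' @param site a [SiteSpec-class].
#' @param targetAreaFraction target ooid area coverage, in (0, 0.9).
#' @param hollowFraction fraction of ooids with dark leached cores.
#' @param nBioclasts number of bioclast contaminants.
#' @param nLayers number of crossbedding bands (0 = none).
#' @param noiseSd additive noise SD (unit gray scale).
#' @param eccentricityMax maximal ellipse axis ratio (1 to 1.3).
#' @return A validated `ImageSpec`.
#' @export
ImageSpec <- function(widthPx, heightPx, pixelSizeUm, site,
                      targetAreaFraction = 0.45, hollowFraction = 0,
                      nBioclasts = 0L, nLayers = 0L, noiseSd = 0,
                      eccentricityMax = 1.2) {
  new("ImageSpec", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), pixelSizeUm = as.numeric(pixelSizeUm),
      targetAreaFraction = as.numeric(targetAreaFraction), site = site,
      hollowFraction = as.numeric(hollowFraction),
      nBioclasts = as.integer(nBioclasts), nLayers = as.integer(nLayers),
      noiseSd = as.numeric(noiseSd),
      eccentricityMax = as.numeric(eccentricityMax))
}

#' Synthetic volume rendering specification
#'
#' Parameters for rendering a 3D grayscale volume of a porous matrix with a
#' few dense sub-spherical (ellipsoidal) inclusions, emulating micro-CT of
#' an oolite bearing iron-oxide concretions. Bright = dense.
#'
#' @slot shapeVox integer(3), volume dimensions in voxels.
#' @slot voxelSizeUm voxel edge length in micrometers.
#' @slot inclusions data.frame with one row per inclusion and columns
#'   `cx, cy, cz` (center, voxel coordinates), `a_mm, b_mm, c_mm` (full axis
#'   lengths in mm), `rx, ry, rz` (orientation, Euler angles in radians) and
#'   `intensity` (gray level, must exceed `matrixIntensity`).
#' @slot matrixIntensity,backgroundIntensity gray levels of the rock matrix
#'   and of empty space.
#' @slot noiseSd additive Gaussian noise SD in gray units.
#' @export
setClass("VolumeSpec",
  representation(
    shapeVox = "integer", voxelSizeUm = "numeric", inclusions = "data.frame",
    matrixIntensity = "numeric", backgroundIntensity = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("VolumeSpec", function(object) {
  msg <- character()
  if (length(object@shapeVox) != 3L || any(object@shapeVox < 4L))
    msg <- c(msg, "shapeVox must be three dimensions, each >= 4")
  if (object@voxelSizeUm <= 0) msg <- c(msg, "voxelSizeUm must be > 0")
  inc <- object@inclusions
  need <- c("cx", "cy", "cz", "a_mm", "b_mm", "c_mm", "rx", "ry", "rz",
            "intensity")
  if (nrow(inc) > 0) {
    if (!all(need %in% names(inc)))
      msg <- c(msg, paste("inclusions must have columns",
                          paste(need, collapse = ", ")))
    else {
      if (any(inc$a_mm <= 0 | inc$b_mm <= 0 | inc$c_mm <= 0))
        msg <- c(msg, "inclusion axes must all be > 0")
      if (any(inc$intensity <= object@matrixIntensity))
        msg <- c(msg, "inclusion intensity must exceed matrixIntensity")
    }
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [VolumeSpec-class]
#'
#' @param shapeVox volume dimensions (3 integers, voxels).
#' @param voxelSizeUm micrometers per voxel.
#' @param inclusions data.frame of inclusion parameters (see
#'   [VolumeSpec-class]); defaults to none.
#' @param matrixIntensity,backgroundIntensity gray levels (unit scale).
#' @param noiseSd additive noise SD.
#' @return A validated `VolumeSpec`.
#' @export
VolumeSpec <- function(shapeVox, voxelSizeUm,
                       inclusions = data.frame(),
                       matrixIntensity = 0.35, backgroundIntensity = 0.05,
                       noiseSd = 0) {
  new("VolumeSpec", shapeVox = as.integer(shapeVox),
      voxelSizeUm = as.numeric(voxelSizeUm), inclusions = inclusions,
      matrixIntensity = as.numeric(matrixIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSd = as.numeric(noiseSd))
}

## ---------------------------------------------------------------------------
## Data classes
## ---------------------------------------------------------------------------

#' A site's measured grain diameters
#'
#' Holds the Feret diameters (mm) measured for one sample, with modality and
#' calibration metadata and provenance of the measurement run.
#'
#' @slot siteId character(1) sample label.
#' @slot modality `"CT"` or `"TS"`.
#' @slot diametersMm numeric vector of grain diameters in mm (all > 0).
#' @slot pixelSizeUm calibration used during measurement (NA if unknown).
#' @slot provenance named list (source file, parameters, seed, ...).
#' @export
setClass("GrainSample",
  representation(
    siteId = "character", modality = "character", diametersMm = "numeric",
    pixelSizeUm = "numeric", provenance = "list"
  )
)

setValidity("GrainSample", function(object) {
  msg <- character()
  if (length(object@siteId) != 1L)
    msg <- c(msg, "siteId must be a single string")
  if (!object@modality %in% c("CT", "TS"))
    msg <- c(msg, "modality must be 'CT' or 'TS'")
  if (length(object@diametersMm) < 1L)
    msg <- c(msg, "diametersMm must be non-empty")
  if (any(!is.finite(object@diametersMm)) || any(object@diametersMm <= 0))
    msg <- c(msg, "all diameters must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [GrainSample-class]
#'
#' @param siteId sample label.
#' @param diametersMm grain diameters in mm.
#' @param modality `"CT"` or `"TS"`.
#' @param pixelSizeUm calibration, micrometers per pixel (NA if unknown).
#' @param provenance named list of run metadata.
#' @return A validated `GrainSample`.
#' @export
GrainSample <- function(siteId, diametersMm, modality = c("CT", "TS"),
                        pixelSizeUm = NA_real_, provenance = list()) {
  modality <- match.arg(modality)
  new("GrainSample", siteId = as.character(siteId),
      modality = modality, diametersMm = as.numeric(diametersMm),
      pixelSizeUm = as.numeric(pixelSizeUm), provenance = provenance)
}

#' Kernel density estimate on a log-diameter grid
#'
#' @slot grid strictly increasing evaluation points (log-mm).
#' @slot density non-negative density values, trapezoid-normalized to unit
#'   integral over `grid`.
#' @slot bandwidth the Gaussian kernel bandwidth used (log units).
#' @slot nSource number of observations the estimate was fitted to.
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric",
                 bandwidth = "numeric", nSource = "integer")
)

setValidity("DensityEstimate", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density must have equal length")
  if (length(object@grid) < 2L)
    msg <- c(msg, "grid must have at least 2 points")
  if (any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (abs(trapz(object@grid, object@density) - 1) > 1e-6)
    msg <- c(msg, "density must integrate to 1 (trapezoid, within 1e-6)")
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Symmetric matrix of pairwise Hellinger distances
#'
#' @slot labels ordered sample labels.
#' @slot values symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
setClass("HellingerMatrix",
  representation(labels = "character", values = "matrix")
)

setValidity("HellingerMatrix", function(object) {
  msg <- character()
  n <- length(object@labels)
  v <- object@values
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "values must be an n x n numeric matrix matching labels")
  else {
    if (anyDuplicated(object@labels))
      msg <- c(msg, "labels must be unique")
    if (any(abs(diag(v)) > 0))
      msg <- c(msg, "diagonal must be exactly zero")
    if (!isTRUE(all.equal(v, t(v), tolerance = 0)) && any(v != t(v)))
      msg <- c(msg, "matrix must be exactly symmetric")
    if (any(v < 0 | v > 1))
      msg <- c(msg, "all entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Principal-coordinate embedding of a distance matrix
#'
#' @slot labels sample labels (row order of `coordinates`).
#' @slot coordinates sites x axes matrix, per-axis centered.
#' @slot eigenvalues all eigenvalues of the double-centered matrix,
#'   descending.
#' @slot varianceExplained per retained axis, fraction of the
#'   positive-eigenvalue total.
#' @slot negativeEigenvalues the negative eigenvalues (possibly empty),
#'   logged for audit; they enter neither coordinates nor the variance
#'   denominator.
#' @export
setClass("OrdinationResult",
  representation(labels = "character", coordinates = "matrix",
                 eigenvalues = "numeric", varianceExplained = "numeric",
                 negativeEigenvalues = "numeric")
)

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (nrow(object@coordinates) != length(object@labels))
    msg <- c(msg, "coordinates must have one row per label")
  if (ncol(object@coordinates) > 0 &&
      any(abs(colSums(object@coordinates)) > 1e-9 *
            max(1, max(abs(object@coordinates)))))
    msg <- c(msg, "coordinates must be centered per axis")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (any(object@varianceExplained < 0 | object@varianceExplained > 1))
    msg <- c(msg, "varianceExplained fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic render
#'
#' @slot diametersMm true diameter (major axis) of each rendered ooid, mm.
#' @slot labelImage integer matrix (2D renders) with ooid ids 1..n, 0 =
#'   background; bioclasts are excluded from the label mask.
#' @slot bioclastMask logical matrix marking bioclast pixels (2D renders).
#' @slot labelVolume integer 3D array (volume renders).
#' @slot axesMm data.frame of true full axis lengths per inclusion
#'   (columns `a_mm >= b_mm >= c_mm`).
#' @slot meta named list (achieved area fraction, placement failures, ...).
#' @export
setClass("GroundTruth",
  representation(diametersMm = "numeric", labelImage = "matrix",
                 bioclastMask = "matrix", labelVolume = "array",
                 axesMm = "data.frame", meta = "list")
)

setValidity("GroundTruth", function(object) {
  lab <- object@labelImage
  if (length(lab) > 1L) {
    ids <- sort(unique(as.integer(lab[lab > 0])))
    if (length(ids) && !identical(ids, seq_along(ids)))
      return("label ids must be consecutive positive integers")
  }
  TRUE
})

#' Calibrated grayscale cross-section image
#'
#' @slot pixels numeric matrix of gray levels (rows = image rows).
#' @slot pixelSizeUm micrometers per pixel (> 0).
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", pixelSizeUm = "numeric")
)

setValidity("GrayImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixels must be a finite numeric matrix")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a [GrayImage-class]
#' @param pixels numeric matrix of gray levels.
#' @param pixelSizeUm micrometers per pixel.
#' @return A validated `GrayImage`.
#' @export
GrayImage <- function(pixels, pixelSizeUm) {
  new("GrayImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Calibrated grayscale volume
#'
#' @slot voxels numeric 3D array of gray levels.
#' @slot voxelSizeUm micrometers per voxel edge (> 0, isotropic).
#' @export
setClass("GrayVolume",
  representation(voxels = "array", voxelSizeUm = "numeric")
)

setValidity("GrayVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@voxelSizeUm) != 1L || object@voxelSizeUm <= 0)
    msg <- c(msg, "voxelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a [GrayVolume-class]
#' @param voxels numeric 3D array of gray levels.
#' @param voxelSizeUm micrometers per voxel edge.
#' @return A validated `GrayVolume`.
#' @export
GrayVolume <- function(voxels, voxelSizeUm) {
  new("GrayVolume", voxels = voxels, voxelSizeUm = as.numeric(voxelSizeUm))
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SiteSpec", function(object) {
  cat("SiteSpec '", object@siteId, "' (", object@modality, "): ",
      length(object@weights), " lognormal component(s), n = ",
      object@nGrains, "\n", sep = "")
})

setMethod("show", "GrainSample", function(object) {
  d <- object@diametersMm
  cat("GrainSample '", object@siteId, "' (", object@modality, "): n = ",
      length(d), ", mean = ", signif(mean(d), 3), " mm, range = [",
      signif(min(d), 3), ", ", signif(max(d), 3), "] mm\n", sep = "")
})

setMethod("show", "DensityEstimate", function(object) {
  cat("DensityEstimate: ", length(object@grid), "-point grid on [",
      signif(min(object@grid), 4), ", ", signif(max(object@grid), 4),
      "] (log mm), bandwidth = ", signif(object@bandwidth, 4),
      ", n = ", object@nSource, "\n", sep = "")
})

setMethod("show", "HellingerMatrix", function(object) {
  cat("HellingerMatrix: ", length(object@labels), " samples\n", sep = "")
  m <- object@values
  dimnames(m) <- list(object@labels, object@labels)
  print(round(m, 3))
})

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult: ", length(object@labels), " sites, ",
      ncol(object@coordinates), " retained axes\n", sep = "")
  if (length(object@varianceExplained))
    cat("  variance explained:",
        paste0(signif(100 * object@varianceExplained, 3), "%",
               collapse = ", "), "\n")
  if (length(object@negativeEigenvalues))
    cat("  dropped", length(object@negativeEigenvalues),
        "negative eigenvalue(s)\n")
})

## ---------------------------------------------------------------------------
## Accessor generics
## ---------------------------------------------------------------------------

#' Grain diameters of a sample
#' @param x a [GrainSample-class].
#' @return numeric vector of diameters in mm.
#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))

#' @rdname diameters
#' @export
setMethod("diameters", "GrainSample", function(x) x@diametersMm)

#' Site label
#' @param x an object carrying a site label.
#' @return character(1).
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname siteId
#' @export
setMethod("siteId", "GrainSample", function(x) x@siteId)

#' @rdname siteId
#' @export
setMethod("siteId", "SiteSpec", function(x) x@siteId)

#' Imaging modality
#' @param x an object carrying a modality.
#' @return `"CT"` or `"TS"`.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname modality
#' @export
setMethod("modality", "GrainSample", function(x) x@modality)

#' @rdname modality
#' @export
setMethod("modality", "SiteSpec", function(x) x@modality)

#' Kernel bandwidth of a density estimate
#' @param x a [DensityEstimate-class].
#' @return numeric(1), log units.
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname bandwidth
#' @export
setMethod("bandwidth", "DensityEstimate", function(x) x@bandwidth)

#' Evaluation grid of a density estimate
#' @param x a [DensityEstimate-class].
#' @return numeric vector (log-mm).
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

#' @rdname densityGrid
#' @export
setMethod("densityGrid", "DensityEstimate", function(x) x@grid)

#' Density values of a density estimate
#' @param x a [DensityEstimate-class].
#' @return numeric vector aligned with [densityGrid()].
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname densityValues
#' @export
setMethod("densityValues", "DensityEstimate", function(x) x@density)

#' Distance-matrix values
#' @param x a [HellingerMatrix-class].
#' @return a labeled symmetric numeric matrix.
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @rdname distanceValues
#' @export
setMethod("distanceValues", "HellingerMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@labels, x@labels)
  m
})

#' Sample labels of a distance matrix or ordination
#' @param x a [HellingerMatrix-class] or [OrdinationResult-class].
#' @return character vector.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "HellingerMatrix", function(x) x@labels)

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "OrdinationResult", function(x) x@labels)

#' Ordination coordinates
#' @param x an [OrdinationResult-class].
#' @return sites x axes numeric matrix.
#' @export
setGeneric("ordCoordinates", function(x) standardGeneric("ordCoordinates"))

#' @rdname ordCoordinates
#' @export
setMethod("ordCoordinates", "OrdinationResult", function(x) {
  m <- x@coordinates
  rownames(m) <- x@labels
  m
})

#' Eigenvalues of an ordination
#' @param x an [OrdinationResult-class].
#' @return numeric vector, descending.
#' @export
setGeneric("ordEigenvalues", function(x) standardGeneric("ordEigenvalues"))

#' @rdname ordEigenvalues
#' @export
setMethod("ordEigenvalues", "OrdinationResult", function(x) x@eigenvalues)

#' Variance explained per retained ordination axis
#' @param x an [OrdinationResult-class].
#' @return numeric vector of fractions of the positive-eigenvalue total.
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "OrdinationResult",
          function(x) x@varianceExplained)
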