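## Image-processing chain from grayscale cross-section to per-ooid Feret
## diameters: binarize -> denoise -> watershed separation -> measurement ->
## shape-based selection. Standard primitives (Otsu, median filters,
## distance transform, h-maxima watershed, hole filling) come from EBImage;
## Feret measurement and the selection logic are implemented here.

#' Pixel-size calibration from a drawn scale bar
#'
#' @param scaleBarPx measured scale-bar length in pixels (> 0).
#' @param scaleBarUm physical scale-bar length in micrometers (> 0).
#' @return micrometers per pixel.
#' @examples
#' calibratePixelSize(87, 1000)  # 11.494 um/px
#' @export
calibratePixelSize <- function(scaleBarPx, scaleBarUm) {
  if (!is.finite(scaleBarPx) || scaleBarPx <= 0 ||
      !is.finite(scaleBarUm) || scaleBarUm <= 0)
    stop("scaleBarPx and scaleBarUm must both be positive")
  scaleBarUm / scaleBarPx
}

#' Binarize a grayscale cross-section
#'
#' Separates the grain phase from the background by a global threshold.
#' With `invert = TRUE` the image contrast is flipped first, so that the
#' grain phase is bright in both micro-CT (dense = bright) and
#' thin-section (grains dark) imagery.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param method `"otsu"` (automatic) or `"fixed"`.
#' @param threshold numeric threshold for `method = "fixed"`; pixels
#'   strictly above it become foreground.
#' @param invert flip contrast before thresholding.
#' @return logical matrix, `TRUE` = grain phase.
#' @export
binarizeImage <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL, invert = FALSE) {
  method <- match.arg(method)
  x <- if (is(image, "GrayImage")) image@pixels else image
  if (!is.matrix(x)) stop("image must be a GrayImage or a numeric matrix")
  if (invert) x <- max(x) + min(x) - x
  if (method == "otsu") {
    rg <- range(x)
    if (diff(rg) == 0)
      stop("Otsu thresholding is undefined on a constant image")
    t <- EBImage::otsu(EBImage::Image(x), range = rg)
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    t <- threshold
  }
  x > t
}

#' Denoise a binary image with a median-filter chain
#'
#' Applies an ordered sequence of the classic binary clean-up filters:
#' `"despeckle"` (3x3 median), `median(radius)` (disc median, i.e. majority
#' vote over a disc neighborhood), `remove_outliers(radius, threshold)`
#' (replace a pixel by the local disc median when it deviates from that
#' median by more than `threshold` on the 0-255 gray convention) and
#' `"fill_holes"` (fill enclosed background, needed when leached ooid cores
#' binarize as holes). The full default chain is idempotent on an already
#' clean solid disc.
#'
#' @param binary logical matrix.
#' @param steps list; each element is `"despeckle"`, `"fill_holes"`, or a
#'   list `list("median", radius = )` / `list("remove_outliers", radius = ,
#'   threshold = )`.
#' @return logical matrix.
#' @export
denoiseBinary <- function(binary,
                          steps = list("despeckle",
                                       list("median", radius = 2),
                                       list("remove_outliers", radius = 2,
                                            threshold = 50))) {
  x <- binary
  if (!is.logical(x)) x <- x > 0
  for (s in steps) {
    if (is.character(s)) s <- list(s)
    x <- switch(s[[1]],
      despeckle = .discMedian(x, radius = 1, square = TRUE),
      median = .discMedian(x, radius = s$radius),
      remove_outliers = {
        med <- .discMedian(x, radius = s$radius)
        dev255 <- abs(as.numeric(x) - as.numeric(med)) * 255
        ifelse(dev255 > s$threshold, med, x)
      },
      fill_holes = .fillHoles(x),
      stop("unknown denoising step: ", s[[1]])
    )
  }
  storage.mode(x) <- "logical"
  dim(x) <- dim(binary)
  x
}

## Majority (median) filter of a binary image over a disc (or 3x3 square)
## neighborhood; an exactly split neighborhood keeps the original value.
.discMedian <- function(x, radius, square = FALSE) {
  k <- if (square) matrix(1, 3, 3) else
    EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  xi <- EBImage::Image(x * 1)
  cnt <- round(EBImage::imageData(
    EBImage::filter2(xi, k, boundary = "replicate")), 6)  # FFT round-off
  s <- sum(k)
  (2 * cnt > s) | (2 * cnt == s & x)
}

.fillHoles <- function(x) {
  filled <- EBImage::fillHull(EBImage::Image(x * 1))
  EBImage::imageData(filled) > 0
}

#' Separate touching grains by distance-transform watershed
#'
#' Computes the Euclidean distance map of the foreground, finds its
#' regional maxima (the ultimate eroded points, with a small h-maxima
#' suppression against pixelation artifacts), and dilates them by watershed
#' flooding. A one-pixel background separation line is carved between
#' adjacent labels, and labels are renumbered consecutively in scan order.
#'
#' @param binary logical matrix (`TRUE` = grain phase).
#' @param tolerance h-maxima depth for marker suppression (distance-map
#'   units, i.e. pixels).
#' @return integer matrix of labels; 0 = background.
#' @export
separateTouching <- function(binary, tolerance = 1) {
  if (!any(binary)) return(matrix(0L, nrow(binary), ncol(binary)))
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- EBImage::imageData(ws)
  storage.mode(lab) <- "integer"
  lab <- .carveSeparationLines(lab)
  .renumberLabels(lab)
}

## Zero every pixel 8-adjacent to a smaller positive label: a deterministic
## one-pixel separation line between touching labels.
.carveSeparationLines <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  cut <- matrix(FALSE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sr <- max(1, 1 + dr):min(n, n + dr)
    tr <- max(1, 1 - dr):min(n, n - dr)
    sc <- max(1, 1 + dc):min(m, m + dc)
    tc <- max(1, 1 - dc):min(m, m - dc)
    nb <- lab[sr, sc, drop = FALSE]
    me <- lab[tr, tc, drop = FALSE]
    hit <- me > 0L & nb > 0L & nb < me
    cut[tr, tc][hit] <- TRUE
  }
  lab[cut] <- 0L
  lab
}

## Renumber positive labels consecutively by first occurrence in
## column-major scan order.
.renumberLabels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  lab
}

#' Measure labeled objects
#'
#' Per object: pixel and physical area, Feret diameter (maximum caliper
#' distance over the corners of the boundary pixels, computed on the convex
#' hull), circularity \eqn{4\pi A / P^2} (capped at 1 against
#' discretization), centroid, and whether the object touches the image
#' frame.
#'
#' @param labels integer matrix of labels (0 = background).
#' @param pixelSizeUm micrometers per pixel.
#' @return data.frame (the object table) with columns `label`, `area_px`,
#'   `area_mm2`, `feret_diameter_mm`, `circularity`, `centroid_row`,
#'   `centroid_col`, `touches_border`, `selected` (initialized `FALSE`).
#' @export
measureObjects <- function(labels, pixelSizeUm) {
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  emptyTab <- data.frame(label = integer(), area_px = integer(),
                         area_mm2 = numeric(), feret_diameter_mm = numeric(),
                         circularity = numeric(), centroid_row = numeric(),
                         centroid_col = numeric(), touches_border = logical(),
                         selected = logical())
  nId <- max(labels)
  if (nId < 1L) return(emptyTab)
  pxMm <- pixelSizeUm / 1000
  pos <- which(labels > 0L, arr.ind = TRUE)
  ids <- labels[pos]
  areaPx <- tabulate(ids, nbins = nId)
  cr <- vapply(split(pos[, 1], ids), mean, 0)
  cc <- vapply(split(pos[, 2], ids), mean, 0)
  onEdge <- pos[, 1] == 1L | pos[, 1] == nrow(labels) |
    pos[, 2] == 1L | pos[, 2] == ncol(labels)
  touches <- vapply(split(onEdge, ids), any, TRUE)

  bnd <- .boundaryMask(labels)
  bpos <- which(bnd, arr.ind = TRUE)
  bids <- labels[bpos]
  byObj <- split(seq_len(nrow(bpos)), bids)
  feretPx <- vapply(byObj, function(ix) {
    feretDiameter(bpos[ix, , drop = FALSE])
  }, 0)

  perim <- .perimeterPx(labels, nId)
  circ <- pmin(1, 4 * pi * areaPx / pmax(perim, 1e-8)^2)

  data.frame(label = seq_len(nId), area_px = areaPx,
             area_mm2 = areaPx * pxMm^2,
             feret_diameter_mm = feretPx * pxMm,
             circularity = circ, centroid_row = unname(cr),
             centroid_col = unname(cc),
             touches_border = unname(touches), selected = FALSE)
}

## Pixels whose 4-neighborhood leaves their object (or the image).
.boundaryMask <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  pad <- matrix(-1L, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- lab
  ctr <- pad[2:(n + 1), 2:(m + 1)]
  out <- ctr > 0L &
    (pad[1:n, 2:(m + 1)] != ctr | pad[3:(n + 2), 2:(m + 1)] != ctr |
     pad[2:(n + 1), 1:m] != ctr | pad[2:(n + 1), 3:(m + 2)] != ctr)
  out
}

#' Feret (maximum caliper) diameter of a pixel set
#'
#' The longest distance between any two points of the object boundary,
#' with each boundary pixel contributing its four corners (pixels are unit
#' squares). Computed exactly via the convex hull; an axis-aligned
#' n x n-pixel square therefore measures \eqn{n\sqrt 2}.
#'
#' @param boundaryPx two-column matrix of boundary pixel (row, col)
#'   coordinates.
#' @return Feret diameter in pixel units.
#' @export
feretDiameter <- function(boundaryPx) {
  r <- boundaryPx[, 1]; c <- boundaryPx[, 2]
  pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  pts <- unique(pts)
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

## Perimeter per object: traced 8-connected contour length (diagonal steps
## sqrt(2)) via EBImage's oriented contours; objects too small to trace get
## the unit-square fallback 4*sqrt(area).
.perimeterPx <- function(lab, nId) {
  perim <- rep(NA_real_, nId)
  oc <- tryCatch(EBImage::ocontour(EBImage::Image(lab)),
                 error = function(e) NULL)
  if (!is.null(oc)) {
    take <- seq_len(min(length(oc), nId))
    for (i in take) {
      p <- oc[[i]]
      if (is.matrix(p) && nrow(p) >= 2) {
        d <- sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2))
        perim[i] <- sum(d)
      }
    }
  }
  area <- tabulate(lab[lab > 0L], nbins = nId)
  fallback <- !is.finite(perim) | perim < 4
  perim[fallback] <- 4 * sqrt(area[fallback])
  perim
}

#' Select clearly identifiable ooids from an object table
#'
#' Keeps objects that pass the area window and the circularity floor and do
#' not touch the image border (border objects are never selected); the
#' survivors' Feret diameters become the sample. Elongated bioclasts and
#' matrix fragments fail the circularity criterion.
#'
#' @param table an object table from [measureObjects()].
#' @param minAreaMm2,maxAreaMm2 area window (mm^2).
#' @param minCircularity circularity floor.
#' @param siteId,modality,pixelSizeUm metadata for the returned sample.
#' @param provenance extra provenance entries (named list).
#' @return A [GrainSample-class]; its provenance records the criteria. The
#'   selected object table is attached as attribute `"objectTable"`.
#' @export
selectOoids <- function(table, minAreaMm2 = 1e-4, maxAreaMm2 = 3,
                        minCircularity = 0.6, siteId = "sample",
                        modality = "CT", pixelSizeUm = NA_real_,
                        provenance = list()) {
  keep <- !table$touches_border &
    table$area_mm2 >= minAreaMm2 & table$area_mm2 <= maxAreaMm2 &
    table$circularity >= minCircularity
  table$selected <- keep
  if (!any(keep))
    stop("no objects pass the selection criteria; review the area window (",
         minAreaMm2, ", ", maxAreaMm2, ") mm^2 and circularity floor ",
         minCircularity)
  sm <- GrainSample(siteId, table$feret_diameter_mm[keep],
                    modality = modality, pixelSizeUm = pixelSizeUm,
                    provenance = c(provenance,
                                   list(minAreaMm2 = minAreaMm2,
                                        maxAreaMm2 = maxAreaMm2,
                                        minCircularity = minCircularity,
                                        nMeasured = nrow(table),
                                        nSelected = sum(keep))))
  attr(sm, "objectTable") <- table
  sm
}

#' Full extraction chain from grayscale image to grain sample
#'
#' Convenience wrapper: [binarizeImage()] -> [denoiseBinary()] ->
#' [separateTouching()] -> [measureObjects()] -> [selectOoids()]. The
#' default denoising chain appends hole filling so leached (hollow) ooids
#' are measured as full grains.
#'
#' @param image a [GrayImage-class].
#' @param siteId,modality sample metadata.
#' @param invert flip contrast before thresholding (thin sections).
#' @param denoiseSteps passed to [denoiseBinary()].
#' @param tolerance watershed h-maxima depth (px).
#' @param minAreaMm2,maxAreaMm2,minCircularity selection criteria.
#' @return A [GrainSample-class] (object table in attribute
#'   `"objectTable"`).
#' @export
extractGrains <- function(image, siteId = "sample", modality = "CT",
                          invert = FALSE,
                          denoiseSteps = list(
                            "despeckle",
                            list("median", radius = 2),
                            list("remove_outliers", radius = 2,
                                 threshold = 50),
                            "fill_holes"),
                          tolerance = 1, minAreaMm2 = 1e-4, maxAreaMm2 = 3,
                          minCircularity = 0.6) {
  stopifnot(is(image, "GrayImage"))
  bin <- binarizeImage(image, method = "otsu", invert = invert)
  bin <- denoiseBinary(bin, steps = denoiseSteps)
  lab <- separateTouching(bin, tolerance = tolerance)
  tab <- measureObjects(lab, image@pixelSizeUm)
  selectOoids(tab, minAreaMm2 = minAreaMm2, maxAreaMm2 = maxAreaMm2,
              minCircularity = minCircularity, siteId = siteId,
              modality = modality, pixelSizeUm = image@pixelSizeUm,
              provenance = list(tolerance = tolerance, invert = invert))
}
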