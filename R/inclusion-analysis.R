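## Dense-inclusion analysis of 3D volumes: half-maximum-height threshold
## from paired probes, 26-connected segmentation, moment-tensor ellipsoid
## axis measurement, and the inclusion-vs-surface-cavity comparison.

#' Half-maximum-height segmentation threshold
#'
#' The midpoint between the median gray levels in small (3x3x3)
#' neighborhoods around one probe inside the object and one in the
#' background.
#'
#' @param volume a [GrayVolume-class] or numeric 3D array.
#' @param objectProbe,backgroundProbe integer(3) voxel coordinates.
#' @return numeric(1) threshold.
#' @export
hmhThreshold <- function(volume, objectProbe, backgroundProbe) {
  v <- if (is(volume, "GrayVolume")) volume@voxels else volume
  dims <- dim(v)
  probeMedian <- function(p) {
    if (any(p < 1) || any(p > dims))
      stop("probe lies outside the volume")
    rng <- lapply(1:3, function(i) max(1, p[i] - 1):min(dims[i], p[i] + 1))
    median(v[rng[[1]], rng[[2]], rng[[3]]])
  }
  mo <- probeMedian(objectProbe)
  mb <- probeMedian(backgroundProbe)
  if (mo == mb)
    stop("object and background probes have equal median intensity (",
         mo, "); cannot place a half-maximum-height threshold")
  (mo + mb) / 2
}

#' Segment dense inclusions above a threshold
#'
#' Labels the 26-connected components of voxels strictly above the
#' threshold and discards components smaller than `minVolumeVox` (noise
#' specks). Labels are consecutive from 1.
#'
#' @param volume a [GrayVolume-class] or numeric 3D array.
#' @param threshold gray-level threshold (e.g. from [hmhThreshold()]).
#' @param minVolumeVox minimum component size in voxels.
#' @return integer 3D array of labels; 0 = background. A warning is raised
#'   when no component survives.
#' @export
segmentInclusions <- function(volume, threshold, minVolumeVox = 27L) {
  v <- if (is(volume, "GrayVolume")) volume@voxels else volume
  lab <- label3d_cpp(v > threshold, dim(v))
  nId <- max(lab)
  if (nId > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nId)
    keep <- which(sizes >= minVolumeVox)
    map <- integer(nId)
    map[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- map[lab[pos]]
    nId <- length(keep)
  }
  if (nId == 0L)
    warning("no inclusion component above the threshold (or all below ",
            minVolumeVox, " voxels)")
  lab
}

#' Principal axis lengths of a voxel component
#'
#' Full extents of the ellipsoid implied by the component's second-moment
#' (covariance) tensor: for a solid uniform ellipsoid the covariance
#' eigenvalues are (semi-axis)^2 / 5, so each axis length is
#' \eqn{2\sqrt{5\lambda}}. A 1/12 within-voxel variance term accounts for
#' voxel extent. Robust to orientation, unlike a bounding box.
#'
#' @param coords matrix of voxel coordinates (rows = voxels, 3 columns).
#' @param voxelSizeUm micrometers per voxel.
#' @return numeric(3): axis lengths a >= b >= c in mm.
#' @export
measureAxes <- function(coords, voxelSizeUm) {
  if (is.null(dim(coords)) || nrow(coords) < 4L)
    stop("component too small to measure")
  cv0 <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  evRaw <- eigen(cv0, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(evRaw, 1e-12) * 1e-9
  if (min(evRaw) <= tol)
    stop("degenerate component: voxels are ",
         if (sum(evRaw > tol) <= 1L) "collinear" else "coplanar",
         "; ellipsoid axes are undefined")
  ev <- eigen(cv0 + diag(1 / 12, 3), symmetric = TRUE,
              only.values = TRUE)$values
  sort(2 * sqrt(5 * ev), decreasing = TRUE) * voxelSizeUm / 1000
}

#' Measure every labeled inclusion in a volume
#'
#' @param labels integer 3D label array (e.g. from [segmentInclusions()]).
#' @param voxelSizeUm micrometers per voxel.
#' @return data.frame (the inclusion table): `label`, axis lengths `a_mm >=
#'   b_mm >= c_mm`, `mean_diameter_mm = (a+b+c)/3`, volume and centroid.
#' @export
measureInclusions <- function(labels, voxelSizeUm) {
  nId <- max(labels)
  out <- data.frame(label = integer(), a_mm = numeric(), b_mm = numeric(),
                    c_mm = numeric(), mean_diameter_mm = numeric(),
                    volume_vox = integer(), centroid_x = numeric(),
                    centroid_y = numeric(), centroid_z = numeric())
  if (nId < 1L) return(out)
  pos <- which(labels > 0L, arr.ind = TRUE)
  ids <- labels[pos]
  for (i in seq_len(nId)) {
    co <- pos[ids == i, , drop = FALSE]
    ax <- measureAxes(co, voxelSizeUm)
    out <- rbind(out, data.frame(
      label = i, a_mm = ax[1], b_mm = ax[2], c_mm = ax[3],
      mean_diameter_mm = mean(ax), volume_vox = nrow(co),
      centroid_x = mean(co[, 1]), centroid_y = mean(co[, 2]),
      centroid_z = mean(co[, 3])))
  }
  out
}

#' Compare embedded inclusions to surface cavities
#'
#' Grand mean of the per-inclusion mean diameters versus the grand mean of
#' the per-cavity mean diameters (cavities are open, so they carry only two
#' in-plane diameters), and their difference. A small difference supports
#' the interpretation that the cavities are broken-out inclusions.
#'
#' @param inclusions data.frame with a `mean_diameter_mm` column (e.g. from
#'   [measureInclusions()]).
#' @param cavities data.frame with columns `d1_mm`, `d2_mm` or a
#'   `mean_diameter_mm` column.
#' @return list: `mean_inclusion_mm`, `mean_cavity_mm`, `difference_mm`
#'   (inclusions minus cavities).
#' @export
compareInclusionsToCavities <- function(inclusions, cavities) {
  if (!nrow(inclusions)) stop("inclusion table is empty")
  if (!nrow(cavities)) stop("cavity table is empty")
  cavMean <- if ("mean_diameter_mm" %in% names(cavities))
    cavities$mean_diameter_mm else (cavities$d1_mm + cavities$d2_mm) / 2
  if (any(cavMean <= 0) || any(inclusions$mean_diameter_mm <= 0))
    stop("diameters must be positive")
  mi <- mean(inclusions$mean_diameter_mm)
  mc <- mean(cavMean)
  list(mean_inclusion_mm = mi, mean_cavity_mm = mc,
       difference_mm = mi - mc)
}
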