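## Plain-text and TIFF interfaces: grain samples and object tables as CSV,
## distance matrices as labeled CSV, density curves as two-column CSV,
## specs as YAML, images as 16-bit grayscale TIFF.

#' Write a grain sample to CSV
#'
#' One row per grain, columns `site_id`, `modality`, `diameter_mm`.
#'
#' @param sample a [GrainSample-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGrainSampleCsv <- function(sample, path) {
  writeCsvStable(data.frame(site_id = siteId(sample),
                            modality = modality(sample),
                            diameter_mm = diameters(sample)), path)
}

#' Read a grain sample from CSV
#'
#' @param path CSV written by [writeGrainSampleCsv()] (columns `site_id`,
#'   `modality`, `diameter_mm`).
#' @return A [GrainSample-class].
#' @export
readGrainSampleCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  GrainSample(df$site_id[1], df$diameter_mm, modality = df$modality[1],
              provenance = list(source = path))
}

#' Write a distance matrix as labeled CSV
#'
#' @param D a [HellingerMatrix-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDistanceMatrixCsv <- function(D, path) {
  m <- distanceValues(D)
  df <- data.frame(site = rownames(m),
                   as.data.frame(formatC(m, digits = 12, format = "g")),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a density estimate as two-column CSV
#'
#' @param d a [DensityEstimate-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDensityCsv <- function(d, path) {
  writeCsvStable(data.frame(log_diameter = densityGrid(d),
                            density = densityValues(d)), path)
}

#' Write a calibrated image as 16-bit grayscale TIFF
#'
#' Gray levels are clamped into `[0, 1]`; the pixel size is stored in the
#' TIFF resolution tags (pixels per centimeter).
#'
#' @param image a [GrayImage-class] or a label matrix (integers are scaled
#'   to the 16-bit range).
#' @param path output file.
#' @param pixelSizeUm required when `image` is a bare matrix.
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(image, path, pixelSizeUm = NULL) {
  if (is(image, "GrayImage")) {
    x <- image@pixels
    pixelSizeUm <- image@pixelSizeUm
  } else {
    x <- image
    if (is.null(pixelSizeUm)) stop("pixelSizeUm required for bare matrices")
    if (max(x) > 1) x <- x / max(x)   # label maps
  }
  x[x < 0] <- 0; x[x > 1] <- 1
  tiff::writeTIFF(x, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF or PNG as a calibrated image
#'
#' @param path image file (`.tif`, `.tiff` or `.png`); multi-channel images
#'   are averaged to gray.
#' @param pixelSizeUm calibration to attach, micrometers per pixel.
#' @return A [GrayImage-class].
#' @export
readGrayImage <- function(path, pixelSizeUm) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
    png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  GrayImage(x, pixelSizeUm)
}

#' Read a site specification from YAML
#'
#' Expected fields: `site_id`, `modality`, `n_grains` and `components`
#' (list of `weight`, `log_mean`, `log_sd`).
#'
#' @param path YAML file.
#' @return A [SiteSpec-class].
#' @export
readSiteSpecYaml <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- y$components
  SiteSpec(y$site_id,
           weights = vapply(comp, `[[`, 0, "weight"),
           logMean = vapply(comp, `[[`, 0, "log_mean"),
           logSd = vapply(comp, `[[`, 0, "log_sd"),
           nGrains = y$n_grains,
           modality = if (is.null(y$modality)) "CT" else y$modality)
}

#' Write a site specification to YAML
#'
#' @param spec a [SiteSpec-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSiteSpecYaml <- function(spec, path) {
  yaml::write_yaml(list(
    site_id = spec@siteId, modality = spec@modality,
    n_grains = spec@nGrains,
    components = lapply(seq_along(spec@weights), function(k) {
      list(weight = spec@weights[k], log_mean = spec@logMean[k],
           log_sd = spec@logSd[k])
    })), path, precision = 15)
  invisible(path)
}
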