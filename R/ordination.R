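## Principal coordinate analysis (classical metric MDS) of a Hellinger
## distance matrix: Gower double-centering, eigendecomposition, positive
## axes only, with a deterministic sign convention and a representation-
## quality diagnostic.

#' Principal coordinate analysis of a distance matrix
#'
#' Double-centers the squared distances, \eqn{B = -\frac12 J D^{(2)} J}
#' with \eqn{J = I - \frac1n 11^\top}, and eigendecomposes \eqn{B}.
#' Coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues; negative eigenvalues (possible for non-Euclidean
#' dissimilarities) are excluded from the coordinates and from the
#' variance-explained denominator and are logged in the result. The sign of
#' each axis is fixed so that its largest-magnitude loading is positive.
#'
#' @param D a [HellingerMatrix-class], or a symmetric zero-diagonal numeric
#'   matrix (optionally with dimnames).
#' @param k number of axes to retain (capped at the number of positive
#'   eigenvalues); default all positive axes.
#' @return An [OrdinationResult-class].
#' @export
runPCoA <- function(D, k = NULL) {
  if (is(D, "HellingerMatrix")) {
    labels <- D@labels
    M <- D@values
  } else {
    M <- as.matrix(D)
    labels <- if (!is.null(rownames(M))) rownames(M) else
      paste0("s", seq_len(nrow(M)))
  }
  n <- nrow(M)
  if (n < 3L) stop("PCoA requires at least 3 samples")
  if (any(abs(M - t(M)) > 1e-12) || any(abs(diag(M)) > 1e-12))
    stop("distance matrix must be symmetric with a zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (M^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  posIdx <- which(ev > tol)
  negEv <- ev[ev < -tol]
  nPos <- length(posIdx)
  if (is.null(k)) k <- nPos
  k <- min(k, nPos)
  coords <- if (k > 0) {
    co <- eg$vectors[, posIdx[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[posIdx[seq_len(k)]]), k)
    for (j in seq_len(k)) {
      if (co[which.max(abs(co[, j])), j] < 0) co[, j] <- -co[, j]
    }
    co
  } else matrix(numeric(0), n, 0)
  colnames(coords) <- if (k > 0) paste0("PCo", seq_len(k)) else character()
  varExp <- if (nPos > 0) ev[posIdx[seq_len(k)]] / sum(ev[posIdx]) else
    numeric(0)
  new("OrdinationResult", labels = labels, coordinates = coords,
      eigenvalues = ev, varianceExplained = varExp,
      negativeEigenvalues = negEv)
}

#' Representation quality of a k-axis embedding
#'
#' Pearson correlation between the original pairwise distances and the
#' pairwise Euclidean distances within the first `k` principal coordinates
#' (upper triangles).
#'
#' @param D the original [HellingerMatrix-class] (or symmetric matrix).
#' @param result an [OrdinationResult-class] from [runPCoA()] on `D`.
#' @param k number of leading axes to use (must not exceed the retained
#'   axes).
#' @return numeric(1), the correlation r.
#' @export
representationQuality <- function(D, result, k) {
  M <- if (is(D, "HellingerMatrix")) D@values else as.matrix(D)
  n <- nrow(M)
  if (n < 3L) stop("correlation undefined for fewer than 3 samples")
  if (k > ncol(result@coordinates))
    stop("k exceeds the number of retained axes (",
         ncol(result@coordinates), ")")
  E <- as.matrix(dist(result@coordinates[, seq_len(k), drop = FALSE]))
  ut <- upper.tri(M)
  cor(M[ut], E[ut])
}
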