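#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers \eqn{-\frac{1}{2} D^2}, eigendecomposes, and scales
#' eigenvectors by the square roots of the positive eigenvalues. Negative
#' eigenvalues (semimetric input) are dropped, not corrected, and variance
#' fractions are computed over the positive spectrum only. Axis signs are
#' fixed by a deterministic convention: the largest-magnitude coordinate on
#' each axis is positive.
#'
#' @param D distance matrix (or `dist`), at least 3 samples.
#' @return an object of class `pcoa_embedding`: list with `labels`,
#'   `coordinates` (n x k, columns `Axis1..Axisk`), `eigenvalues` (positive,
#'   descending) and `variance_explained` (fractions summing to 1 over the
#'   retained axes).
#' @export
pcoa <- function(D) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples, got ", n)
  cs <- suppressWarnings(cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- cs$eig
  if (max(eig) <= 0)
    stop("degenerate distance matrix: no positive eigenvalue")
  tol <- max(eig) * 1e-9
  k <- min(sum(eig > tol), ncol(cs$points))
  coords <- cs$points[, seq_len(k), drop = FALSE]
  # sign convention: largest-|coordinate| entry positive on every axis
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  eigv <- eig[seq_len(k)]
  colnames(coords) <- paste0("Axis", seq_len(k))
  rownames(coords) <- rownames(D)
  structure(list(labels = rownames(D),
                 coordinates = coords,
                 eigenvalues = eigv,
                 variance_explained = eigv / sum(eigv)),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat(sprintf("PCoA embedding: %d samples, %d axes; axis-1 variance %.1f%%\n",
              length(x$labels), ncol(x$coordinates),
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Number of ordination axes needed to reach a variance threshold
#'
#' Smallest axis count whose cumulative variance (over positive eigenvalues)
#' exceeds `threshold`, capped at `cap` and at the number of available axes;
#' always at least 1.
#'
#' @param embedding a `pcoa_embedding`.
#' @param threshold cumulative variance fraction to exceed (default 0.8).
#' @param cap maximum number of axes (default 10).
#' @export
dims_for_variance <- function(embedding, threshold = 0.8, cap = 10) {
  stopifnot(inherits(embedding, "pcoa_embedding"),
            threshold > 0, threshold < 1, cap >= 1)
  cum <- cumsum(embedding$variance_explained)
  hit <- which(cum > threshold)
  nd <- if (length(hit)) hit[1] else length(cum)
  max(1L, min(nd, cap, length(cum)))
}

#' Correlation between an ordination axis and a known gradient
#'
#' Absolute Pearson correlation between the coordinates on one axis and an
#' external gradient variable (pH, depth, time, simulated position...).
#' Absolute because the sign of a PCoA axis is arbitrary.
#'
#' @param embedding a `pcoa_embedding`.
#' @param gradient numeric vector, one value per sample, non-constant.
#' @param axis axis number (default 1).
#' @export
axis_gradient_correlation <- function(embedding, gradient, axis = 1) {
  stopifnot(inherits(embedding, "pcoa_embedding"))
  if (length(gradient) != length(embedding$labels))
    stop("gradient length must equal the number of samples")
  if (axis < 1 || axis > ncol(embedding$coordinates))
    stop("axis ", axis, " not available in the embedding")
  if (sd(gradient) == 0) stop("gradient is constant; correlation undefined")
  abs(cor(embedding$coordinates[, axis], gradient))
}

#' Diagnose oversaturated pairwise distances
#'
#' Oversaturation — distances piled up near the measure's upper range, with
#' a thin left tail — shows up as negative (left) skew of the off-diagonal
#' distance distribution, and is the situation in which manifold adjustment
#' helps. The adjusted Fisher-Pearson sample skewness of the upper-triangle
#' values is reported together with a boolean verdict at `skew_cutoff`; the
#' cutoff is a pragmatic default, and the numeric skewness is always
#' returned so users can apply their own.
#'
#' @param D distance matrix (or `dist`), at least 4 samples.
#' @param skew_cutoff verdict threshold (default -0.1): oversaturated when
#'   skewness falls below it.
#' @return list with `skewness` and logical `oversaturated`.
#' @export
oversaturation_check <- function(D, skew_cutoff = -0.1) {
  D <- as_distance_matrix(D)
  if (nrow(D) < 4) stop("oversaturation check needs at least 4 samples")
  v <- D[upper.tri(D)]
  if (sd(v) == 0) {
    warning("zero variance of pairwise distances; skewness undefined")
    return(list(skewness = 0, oversaturated = FALSE))
  }
  sk <- unname(e1071::skewness(v, type = 2))
  list(skewness = sk, oversaturated = sk < skew_cutoff)
}

#' Write a PCoA embedding as tab-separated text
#'
#' Writes coordinates (sample, Axis1..AxisK) to `path`, and optionally the
#' eigenvalue / variance-explained table to `eigen_path`.
#'
#' @param embedding a `pcoa_embedding`.
#' @param path coordinates output path.
#' @param eigen_path optional eigenvalue table output path.
#' @export
write_embedding <- function(embedding, path, eigen_path = NULL) {
  stopifnot(inherits(embedding, "pcoa_embedding"))
  write.table(embedding$coordinates, file = path, sep = "\t", quote = FALSE,
              col.names = NA)
  if (!is.null(eigen_path)) {
    tab <- data.frame(axis = seq_along(embedding$eigenvalues),
                      eigenvalue = embedding$eigenvalues,
                      variance_explained = embedding$variance_explained)
    write.table(tab, file = eigen_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(embedding)
}
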