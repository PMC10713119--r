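#' Coerce and validate a pairwise distance matrix
#'
#' The package's common currency is a labeled square symmetric matrix of
#' nonnegative dissimilarities with a zero diagonal. `as_distance_matrix()`
#' accepts a `dist` object or a square numeric matrix, checks the
#' invariants, and returns a plain labeled matrix. Small asymmetries (up to
#' `tol`, e.g. from serialization round trips) are repaired by averaging
#' `(M + t(M)) / 2`; anything larger is an error, as is any negative,
#' non-finite, or nonzero-diagonal entry beyond `tol`.
#'
#' @param x a `dist` object or square numeric matrix.
#' @param tol tolerance for asymmetry and diagonal deviations (default 1e-8).
#' @return a square numeric matrix with unique row/column labels, exactly
#'   symmetric, zero diagonal, all entries finite and nonnegative.
#' @examples
#' as_distance_matrix(dist(matrix(rnorm(12), 4)))
#' @export
as_distance_matrix <- function(x, tol = 1e-8) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("distance input must be a numeric matrix or 'dist' object")
  if (nrow(x) != ncol(x))
    stop("distance matrix must be square, got ", nrow(x), "x", ncol(x))
  if (any(!is.finite(x)))
    stop("distance matrix contains non-finite entries")
  if (any(x < 0))
    stop("distance matrix contains negative entries")
  if (max(abs(x - t(x))) > tol)
    stop("distance matrix is asymmetric beyond tolerance ", tol)
  if (max(abs(diag(x))) > tol)
    stop("distance matrix diagonal deviates from zero beyond tolerance ", tol)
  x <- (x + t(x)) / 2
  diag(x) <- 0
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(labs)) stop("sample labels must be unique")
  cl <- colnames(x)
  if (!is.null(cl) && !identical(cl, labs))
    stop("row and column labels disagree")
  dimnames(x) <- list(labs, labs)
  x
}

#' Read a distance matrix from a labeled tab-separated file
#'
#' Expects a square body with identical sample labels as the first row and
#' first column (the format written by [write_distance_matrix()]).
#'
#' @param path file path.
#' @param tol asymmetry tolerance passed to [as_distance_matrix()].
#' @return a validated distance matrix.
#' @export
read_distance_matrix <- function(path, tol = 1e-8) {
  df <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE,
                   sep = "\t", quote = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("distance matrix body must be numeric: ", path)
  if (nrow(m) != ncol(m))
    stop("distance matrix file is not square: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ in ", path)
  as_distance_matrix(m, tol = tol)
}

#' Write a distance matrix as a labeled tab-separated file
#'
#' @param D distance matrix (or `dist`).
#' @param path output file path.
#' @return invisibly, the validated matrix that was written.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as_distance_matrix(D)
  write.table(D, file = path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(D)
}
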