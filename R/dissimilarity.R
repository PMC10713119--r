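#' Read a samples-by-features abundance table
#'
#' Tab-separated, samples as rows with labels in the first column, feature
#' names in the header. Entries may be counts or relative abundances; they
#' must be finite and nonnegative and no sample row may sum to zero.
#'
#' @param path file path.
#' @return a numeric matrix (samples x features) with dimnames.
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE,
                   sep = "\t", quote = "")
  m <- as.matrix(df)
  validate_abundance_table(m)
}

#' Write an abundance table as tab-separated text
#'
#' @param tab samples-by-features numeric matrix.
#' @param path output file path.
#' @export
write_abundance_table <- function(tab, path) {
  tab <- validate_abundance_table(tab)
  write.table(tab, file = path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(tab)
}

validate_abundance_table <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab) || !is.numeric(tab))
    stop("abundance table must be a numeric matrix")
  if (any(!is.finite(tab))) stop("abundance table has non-finite entries")
  if (any(tab < 0)) stop("abundance table has negative entries")
  if (any(rowSums(tab) == 0))
    stop("abundance table has empty sample rows (zero total abundance)")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("S", seq_len(nrow(tab)))
  tab
}

#' Bray-Curtis dissimilarity
#'
#' Rows are first normalized to relative abundances, then
#' \eqn{BC(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)} is computed for
#' every sample pair. Values lie in \[0, 1\]; 0 for identical compositions,
#' 1 for disjoint feature support.
#'
#' @param tab samples-by-features abundance matrix (counts or proportions).
#' @return a distance matrix (see [as_distance_matrix()]).
#' @export
bray_curtis <- function(tab) {
  tab <- validate_abundance_table(tab)
  rel <- tab / rowSums(tab)
  as_distance_matrix(as.matrix(vegan::vegdist(rel, method = "bray")))
}

#' Binary Jaccard dissimilarity
#'
#' Features are binarized at abundance > 0 and the classical set form
#' \eqn{1 - |A \cap B| / |A \cup B|} is computed on presence sets. This is
#' the presence/absence Jaccard, not the abundance-weighted variant.
#'
#' @inheritParams bray_curtis
#' @return a distance matrix with entries in \[0, 1\].
#' @export
jaccard <- function(tab) {
  tab <- validate_abundance_table(tab)
  as_distance_matrix(as.matrix(vegan::vegdist(tab, method = "jaccard",
                                              binary = TRUE)))
}
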