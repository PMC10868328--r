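#' Validate and coerce a genes-by-cells count matrix
#'
#' Coerces a dense or sparse matrix of single-cell counts to the sparse
#' `dgCMatrix` representation used throughout the package (genes as rows,
#' cells as columns) and enforces the contract the normalization relies on:
#' all entries non-negative integers, at least one gene and two cells, and
#' every cell with at least one non-zero count. Cells with all-zero counts
#' have no defined size factor and are rejected by name rather than silently
#' dropped, so cell identifiers never desynchronize from columns.
#'
#' @param counts A numeric matrix or `Matrix::sparseMatrix` of counts with
#'   genes as rows and cells as columns. Row names (gene ids) and column
#'   names (cell ids) are kept if present, otherwise `gene1..geneG` /
#'   `cell1..celln` are assigned.
#'
#' @return A `dgCMatrix` with gene ids as rownames and cell ids as colnames.
#' @examples
#' y <- matrix(rpois(60, 5), nrow = 10)
#' validate_counts(y)
#' @export
validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!methods::is(counts, "Matrix") && !is.matrix(counts))
    stop("'counts' must be a matrix or sparse Matrix", call. = FALSE)
  m <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop("count matrix must have >= 1 gene and >= 2 cells", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("cell", seq_len(ncol(m)))
  x <- m@x
  if (length(x) && (anyNA(x) || any(!is.finite(x))))
    stop("count matrix contains missing or non-finite entries", call. = FALSE)
  if (length(x) && any(x < 0))
    stop("count matrix contains negative entries", call. = FALSE)
  if (length(x) && any(abs(x - round(x)) > 1e-8)) {
    bad <- which(abs(x - round(x)) > 1e-8)[1L]
    j <- sum(m@p < bad)  # column holding the offending entry
    stop(sprintf("count matrix contains non-integer entries (first in cell '%s')",
                 colnames(m)[j]), call. = FALSE)
  }
  m@x <- round(x)
  m <- Matrix::drop0(m)
  zero_cells <- Matrix::colSums(m) == 0
  if (any(zero_cells)) {
    ids <- colnames(m)[zero_cells]
    stop(sprintf("cells with all-zero counts cannot be normalized: %s",
                 paste(utils::head(ids, 10L), collapse = ", ")), call. = FALSE)
  }
  m
}
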