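#' Median-ratio size factors from pseudo-profiles and references
#'
#' Step 4 of the normalization: each cell's size factor is the median, over
#' its non-zero genes, of the ratio of its pseudo-profile to the per-gene
#' reference, \eqn{\theta_j = median\{a_{gj} / m_g : g \in R_j\}}. Under the
#' non-DE assumption this median ratio isolates the cell's technical scale.
#' The median of an even-length set is the mean of the two middle values.
#'
#' @param pseudo A `dgCMatrix` of pseudo-profile values at the non-zero
#'   positions of the count matrix (the `a` component of
#'   [pseudo_profiles()]).
#' @param reference Per-gene reference values from [reference_values()].
#' @param rescale If `TRUE` (default) the raw factors are rescaled so their
#'   geometric mean over cells is 1, making normalized magnitudes comparable
#'   to raw counts.
#' @return Named numeric vector of positive size factors, one per cell.
#' @examples
#' y <- matrix(rpois(200, 5) + 1, nrow = 20)
#' ax <- technical_axis(nonzero_log_quantiles(y))
#' pp <- pseudo_profiles(y, ax$r)
#' size_factors(pp$a, reference_values(y))
#' @export
size_factors <- function(pseudo, reference, rescale = TRUE) {
  a <- methods::as(methods::as(pseudo, "generalMatrix"), "CsparseMatrix")
  if (length(reference) != nrow(a))
    stop("'reference' must have one value per gene", call. = FALSE)
  n <- ncol(a)
  p <- a@p
  theta <- numeric(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] == p[j])
      stop(sprintf("cell '%s' has no non-zero genes", colnames(a)[j]), call. = FALSE)
    idx <- (p[j] + 1L):p[j + 1L]
    ratio <- a@x[idx] / reference[a@i[idx] + 1L]
    if (anyNA(ratio) || any(!is.finite(ratio))) {
      k <- idx[which(!is.finite(ratio))[1L]]
      stop(sprintf("non-finite pseudo/reference ratio at gene '%s', cell '%s'",
                   rownames(a)[a@i[k] + 1L], colnames(a)[j]), call. = FALSE)
    }
    theta[j] <- median(ratio)
  }
  names(theta) <- colnames(a)
  if (rescale) theta <- rescale_geomean(theta)
  theta
}

#' Kernel-weighted-average robust normalization
#'
#' Estimates a per-cell global size factor from a raw count matrix without
#' assuming a count distribution or a count-depth relationship, in four
#' steps:
#' \enumerate{
#'   \item summarize each cell by the 25th/50th/75th percentiles of its log
#'     non-zero counts and project the summaries onto their first principal
#'     component, the technical axis `r` ([nonzero_log_quantiles()],
#'     [technical_axis()]);
#'   \item build each cell's pseudo expression profile by kernel-weighted
#'     geometric averaging of every non-zero gene over the gene's expressing
#'     cells, with gene-specific Sheather-Jones bandwidths over `r`
#'     ([pseudo_profiles()]);
#'   \item build the per-gene reference as the geometric mean of non-zero
#'     counts ([reference_values()]);
#'   \item take the median ratio of pseudo-profile to reference over each
#'     cell's non-zero genes ([size_factors()]).
#' }
#' The computation is fully deterministic: identical inputs and options give
#' bit-identical factors.
#'
#' @param counts Genes-by-cells count matrix: a base matrix, a sparse
#'   `Matrix`, or a data.frame of counts. All entries must be non-negative
#'   integers and every cell must have at least one non-zero count.
#' @param cutoff Kernel truncation factor (default 2): donor weights beyond
#'   `cutoff * h_g` on the technical axis are zeroed before renormalization,
#'   saving time with negligible effect on the factors. `NULL` or `Inf`
#'   disables truncation.
#' @param rescale If `TRUE` (default), size factors are rescaled to geometric
#'   mean 1 across cells.
#' @param return_normalized If `TRUE`, also return the normalized matrix
#'   `counts / theta[j]` (sparse).
#' @return An object of class `sckwarn_norm`: a list with
#' \describe{
#'   \item{theta}{named per-cell size factors (positive, geometric mean 1
#'     when `rescale = TRUE`);}
#'   \item{reference}{per-gene reference values `m_g` (`NA` for all-zero
#'     genes);}
#'   \item{bandwidths}{per-gene bandwidth table with fallback annotations;}
#'   \item{r, pc1_variance_fraction}{the technical axis and its variance
#'     share;}
#'   \item{options}{the cutoff and rescaling convention used;}
#'   \item{normalized}{the normalized matrix (only if requested).}
#' }
#' @examples
#' set.seed(1)
#' y <- matrix(rnbinom(3000, mu = 4, size = 2), nrow = 150)
#' fit <- sckwarn(y)
#' head(fit$theta)
#' @export
sckwarn <- function(counts, cutoff = 2, rescale = TRUE, return_normalized = FALSE) {
  m <- validate_counts(counts)
  Q <- nonzero_log_quantiles(m)
  axis <- technical_axis(Q)
  pp <- pseudo_profiles(m, axis$r, cutoff = cutoff)
  ref <- reference_values(m)
  theta <- size_factors(pp$a, ref, rescale = rescale)
  res <- list(theta = theta,
              reference = ref,
              bandwidths = pp$bandwidths,
              r = axis$r,
              pc1_variance_fraction = axis$pc1_variance_fraction,
              options = list(cutoff = if (is.null(cutoff)) Inf else cutoff,
                             rescale = if (rescale) "geometric_mean_1" else "none"))
  if (return_normalized) res$normalized <- normalize_counts(m, theta)
  structure(res, class = "sckwarn_norm")
}

#' @export
print.sckwarn_norm <- function(x, ...) {
  cat(sprintf("sckwarn normalization: %d cells, %d genes\n",
              length(x$theta), length(x$reference)))
  cat(sprintf("  cutoff: %s; rescaling: %s\n",
              format(x$options$cutoff), x$options$rescale))
  cat(sprintf("  technical axis PC1 variance fraction: %.3f\n",
              x$pc1_variance_fraction))
  fbt <- table(x$bandwidths$fallback)
  cat("  bandwidths:", paste(sprintf("%s=%d", names(fbt), fbt), collapse = ", "), "\n")
  cat("  size factors:\n")
  print(summary(x$theta))
  invisible(x)
}

#' Divide counts by per-cell size factors
#'
#' @param counts Genes-by-cells count matrix.
#' @param theta Positive per-cell size factors.
#' @return Sparse matrix of `counts[, j] / theta[j]`.
#' @export
normalize_counts <- function(counts, theta) {
  m <- validate_counts(counts)
  if (length(theta) != ncol(m) || any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' must be positive and finite, one value per cell", call. = FALSE)
  out <- m %*% Matrix::Diagonal(x = 1 / theta)
  dimnames(out) <- dimnames(m)
  out
}

#' Relative-counts (library-size) size factors
#'
#' The simplest global-scaling baseline: size factors proportional to each
#' cell's total count (its library size), rescaled to geometric mean 1. Used
#' as the comparison baseline in the benchmarking functions.
#'
#' @param counts Genes-by-cells count matrix.
#' @return Named numeric vector of positive size factors with geometric
#'   mean 1.
#' @export
relative_counts <- function(counts) {
  m <- validate_counts(counts)
  rescale_geomean(Matrix::colSums(m))
}
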