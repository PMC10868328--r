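#' Gaussian kernel weights over a gene's expressing cells
#'
#' For one gene, computes the normalized Gaussian kernel weights that each
#' target cell places on the gene's donor (expressing) cells, as a function of
#' distance along the technical axis: raw weight
#' \eqn{\exp(-(r_j - r_{j'})^2 / (2 h_g^2))}, renormalized to sum to 1 over
#' donors. With a finite `cutoff`, raw weights are set to 0 where
#' \eqn{|r_j - r_{j'}| > cutoff \cdot h_g} before renormalization; if that
#' empties all donors for a target, the single nearest donor receives weight 1
#' so the pseudo-profile is never undefined.
#'
#' @param r Numeric vector of technical-axis coordinates for all cells.
#' @param expressing Integer indices (into `r`) of the cells expressing the
#'   gene (the donors), non-empty.
#' @param h Positive bandwidth.
#' @param cutoff Positive cutoff factor, or `NULL`/`Inf` to disable
#'   truncation. Default 2.
#' @param targets Integer indices of target cells (rows of the result).
#'   Defaults to all cells.
#' @return A `length(targets) x length(expressing)` matrix of weights; each
#'   row is non-negative and sums to 1.
#' @examples
#' r <- c(0, 1, 5)
#' gene_kernel_weights(r, expressing = 1:3, h = 1, cutoff = 2, targets = 1L)
#' @export
gene_kernel_weights <- function(r, expressing, h, cutoff = 2, targets = seq_along(r)) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a positive finite scalar", call. = FALSE)
  expressing <- as.integer(expressing)
  if (length(expressing) == 0L) stop("'expressing' must be non-empty", call. = FALSE)
  cutoff <- if (is.null(cutoff)) Inf else as.numeric(cutoff)
  if (cutoff <= 0) stop("'cutoff' must be positive (or NULL to disable)", call. = FALSE)
  d <- abs(outer(r[targets], r[expressing], "-"))
  W <- exp(-d^2 / (2 * h^2))
  if (is.finite(cutoff)) W[d > cutoff * h] <- 0
  empty <- rowSums(W) == 0
  if (any(empty)) {
    for (i in which(empty)) W[i, which.min(d[i, ])] <- 1
  }
  W / rowSums(W)
}

#' Kernel-weighted pseudo expression profiles
#'
#' Builds each cell's pseudo expression profile: for every non-zero position
#' `(g, j)` of the count matrix, the kernel-weighted geometric mean
#' \eqn{a_{gj} = \exp(\sum_{j' \in C_g} w_{g,(j,j')} \log y_{gj'})} of the
#' gene's counts over its expressing cells, weighted by proximity to cell `j`
#' on the technical axis. The per-gene kernel bandwidth is the Sheather-Jones
#' bandwidth of the expressing cells' `r` coordinates (see [sj_bandwidth()]
#' for the fallback chain); genes expressed in a single cell bypass bandwidth
#' selection, their only donor receiving weight 1.
#'
#' Pseudo-profiles exist only at the non-zero positions of the count matrix
#' and are stored sparsely; no dense genes-by-cells intermediate is ever
#' allocated.
#'
#' @param counts Genes-by-cells count matrix (anything [validate_counts()]
#'   accepts).
#' @param r Technical-axis coordinates, one per cell (see [technical_axis()]).
#' @param cutoff Kernel truncation factor (default 2): donor weights are
#'   zeroed beyond `cutoff * h_g` before renormalization. `NULL` or `Inf`
#'   disables truncation and reproduces the untruncated computation exactly.
#' @return A list with `a` (a `dgCMatrix` with the sparsity pattern of
#'   `counts`, holding the `a[g, j]` values) and `bandwidths` (a data.frame
#'   with one row per gene: `gene_id`, `n_expressing`, `bandwidth`,
#'   `fallback`; all-zero genes get `NA` bandwidth and fallback `"unexpressed"`,
#'   single-donor genes `"single"`).
#' @examples
#' y <- matrix(rpois(200, 5), nrow = 20)
#' ax <- technical_axis(nonzero_log_quantiles(y))
#' pp <- pseudo_profiles(y, ax$r)
#' @export
pseudo_profiles <- function(counts, r, cutoff = 2) {
  m <- validate_counts(counts)
  n <- ncol(m); G <- nrow(m)
  if (length(r) != n) stop("'r' must have one coordinate per cell", call. = FALSE)
  cutoff <- if (is.null(cutoff)) Inf else as.numeric(cutoff)
  if (cutoff <= 0) stop("'cutoff' must be positive (or NULL to disable)", call. = FALSE)
  r_range <- diff(range(r))

  tc <- Matrix::t(m)                    # cells x genes; one gene per column
  p <- tc@p; idx_cell <- tc@i; xs <- tc@x
  ax <- numeric(length(xs))
  bw <- rep(NA_real_, G)
  fb <- rep("unexpressed", G)
  for (g in seq_len(G)) {
    if (p[g + 1L] == p[g]) next
    idx <- (p[g] + 1L):p[g + 1L]
    y <- xs[idx]
    if (length(idx) == 1L) {            # single donor keeps its own count
      ax[idx] <- y
      fb[g] <- "single"
      next
    }
    rg <- r[idx_cell[idx] + 1L]
    sj <- sj_bandwidth(rg, r_range = r_range)
    bw[g] <- sj$bandwidth
    fb[g] <- sj$fallback
    ax[idx] <- .cpp_kernel_smooth_gene(rg, log(y), sj$bandwidth, cutoff)
  }
  ta <- methods::new("dgCMatrix", i = tc@i, p = tc@p, x = ax, Dim = tc@Dim,
                     Dimnames = tc@Dimnames)
  list(a = Matrix::t(ta),
       bandwidths = data.frame(gene_id = rownames(m),
                               n_expressing = diff(p),
                               bandwidth = bw,
                               fallback = fb,
                               stringsAsFactors = FALSE))
}

#' Per-gene reference values
#'
#' The reference value of gene `g` is the geometric mean of its non-zero
#' counts, \eqn{m_g = \exp(\sum_{j \in C_g} \log y_{gj} / |C_g|)}. Restricting
#' to expressing cells avoids the all-zero geometric-mean collapse that makes
#' bulk median-ratio references unusable on sparse single-cell data; the
#' cell-specific reference profile `M_j` is simply `m_g` restricted to the
#' genes non-zero in cell `j`. Genes expressed nowhere carry no reference and
#' are returned as `NA`.
#'
#' @param counts Genes-by-cells count matrix.
#' @return Named numeric vector of length `G` (`NA` for all-zero genes).
#' @examples
#' reference_values(matrix(c(2, 8, 0, 5), nrow = 2))  # gene1: sqrt(16) = 4
#' @export
reference_values <- function(counts) {
  m <- validate_counts(counts)
  lm <- m
  lm@x <- log(m@x)
  s <- Matrix::rowSums(lm)
  nnz <- tabulate(m@i + 1L, nbins = nrow(m))
  ref <- ifelse(nnz > 0L, exp(s / nnz), NA_real_)
  names(ref) <- rownames(m)
  ref
}
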