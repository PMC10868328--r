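#' Per-cell quantile summaries of log non-zero counts
#'
#' Summarizes each cell's non-zero count distribution by the 25th, 50th and
#' 75th percentiles of its natural-log counts. These three quantiles capture
#' the location and spread of the expressed part of the transcriptome while
#' staying robust to highly expressed and differentially expressed genes;
#' they are the raw material for the technical axis used to define fuzzy
#' technical neighbors.
#'
#' Quantiles use the linear-interpolation convention (type 7, the [quantile()]
#' default), fixed so results are bit-stable across runs.
#'
#' @param counts A genes-by-cells count matrix (anything [validate_counts()]
#'   accepts).
#' @return An `n x 3` matrix `Q`; row `j` holds the 25th/50th/75th percentiles
#'   of `log(y[g, j])` over genes `g` with `y[g, j] > 0`. Rownames are cell
#'   ids, colnames `c("q25", "q50", "q75")`.
#' @seealso [technical_axis()]
#' @examples
#' y <- matrix(rpois(200, 8), nrow = 20)
#' Q <- nonzero_log_quantiles(y)
#' head(Q)
#' @export
nonzero_log_quantiles <- function(counts) {
  m <- validate_counts(counts)
  n <- ncol(m)
  p <- m@p
  lx <- log(m@x)
  Q <- matrix(NA_real_, n, 3L, dimnames = list(colnames(m), c("q25", "q50", "q75")))
  for (j in seq_len(n)) {
    v <- lx[(p[j] + 1L):p[j + 1L]]
    Q[j, ] <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }
  Q
}

#' Technical axis: first principal component of the quantile summaries
#'
#' Projects the per-cell quantile matrix `Q` onto its first principal axis.
#' The resulting scalar coordinate `r[j]` orders cells by their dominant mode
#' of technical variation (depth, capture efficiency, dropout), and distances
#' `|r[j] - r[j']|` define technical similarity between cells.
#'
#' Columns of `Q` are mean-centered but not variance-scaled: all three live on
#' the same log-count scale, and scaling would distort the location/spread
#' trade-off. PC1 is taken from the eigendecomposition of the 3x3 covariance
#' of the centered columns. The sign of `r` is arbitrary (eigenvector sign);
#' everything downstream uses only pairwise distances, which are
#' sign-invariant. If `Q` carries no variance at all, `r` is the zero vector
#' and the variance fraction is reported as 1.
#'
#' @param Q An `n x 3` numeric matrix as produced by
#'   [nonzero_log_quantiles()] (`n >= 2`, all entries finite).
#' @return A list with `r` (length-`n` PC1 scores, mean 0) and
#'   `pc1_variance_fraction` (share of total variance on PC1, in `[0, 1]`).
#' @examples
#' y <- matrix(rpois(200, 8), nrow = 20)
#' ax <- technical_axis(nonzero_log_quantiles(y))
#' ax$pc1_variance_fraction
#' @export
technical_axis <- function(Q) {
  Q <- as.matrix(Q)
  if (!is.numeric(Q) || ncol(Q) != 3L)
    stop("'Q' must be a numeric n x 3 matrix", call. = FALSE)
  if (nrow(Q) < 2L) stop("'Q' must have at least 2 rows (cells)", call. = FALSE)
  if (anyNA(Q) || any(!is.finite(Q)))
    stop("'Q' contains non-finite entries", call. = FALSE)
  Qc <- sweep(Q, 2L, colMeans(Q), "-")
  cv <- crossprod(Qc) / (nrow(Q) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  tot <- sum(lambda)
  if (tot <= 0) {
    return(list(r = stats::setNames(rep(0, nrow(Q)), rownames(Q)),
                pc1_variance_fraction = 1))
  }
  r <- drop(Qc %*% ev$vectors[, 1L])
  names(r) <- rownames(Q)
  list(r = r, pc1_variance_fraction = lambda[1L] / tot)
}
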