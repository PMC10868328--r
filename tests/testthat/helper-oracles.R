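# Independent oracles used to cross-check the implementation. These are
# deliberately naive (double loops, dense algebra, plain bisection) and share
# no code with the package internals.

# Sheather-Jones solve-the-equation bandwidth, brute force: full pairwise
# difference matrix, exact functional sums, bisection refined far below the
# comparison tolerance.
oracle_sj_bandwidth <- function(x) {
  n <- length(x)
  dif <- abs(outer(x, x, "-"))[lower.tri(diag(n))]
  phi4 <- function(t) (t^4 - 6 * t^2 + 3) * exp(-t^2 / 2)
  phi6 <- function(t) (t^6 - 15 * t^4 + 45 * t^2 - 15) * exp(-t^2 / 2)
  SD <- function(h) (2 * sum(phi4(dif / h)) + n * 3) / (n * (n - 1) * h^5 * sqrt(2 * pi))
  TD <- function(h) (2 * sum(phi6(dif / h)) - 15 * n) / (n * (n - 1) * h^7 * sqrt(2 * pi))
  scale <- min(sd(x), IQR(x) / 1.349)
  a <- 1.24 * scale * n^(-1 / 7)
  b <- 1.23 * scale * n^(-1 / 9)
  c1 <- 1 / (2 * sqrt(pi) * n)
  TDb <- -TD(b)
  stopifnot(is.finite(TDb), TDb > 0)
  alph2 <- 1.357 * (SD(a) / TDb)^(1 / 7)
  fSD <- function(h) (c1 / SD(alph2 * h^(5 / 7)))^(1 / 5) - h
  h0 <- 0.9 * scale * n^(-1 / 5)
  lo <- h0 / 256; hi <- h0 * 256
  flo <- fSD(lo); fhi <- fSD(hi)
  stopifnot(flo * fhi < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- fSD(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    if ((hi - lo) < 1e-13 * h0) break
  }
  (lo + hi) / 2
}

# Brute-force pseudo-profiles and size factors: dense double loops over all
# genes, targets and donors, recomputing Gaussian weights from scratch.
# Bandwidths (one per gene, NA for single-donor genes) are taken as given so
# the check isolates the kernel-averaging and median-ratio machinery.
oracle_normalize <- function(counts, r, bandwidths, cutoff = Inf) {
  y <- as.matrix(counts)
  G <- nrow(y); n <- ncol(y)
  a <- matrix(NA_real_, G, n)
  for (g in seq_len(G)) {
    donors <- which(y[g, ] > 0)
    if (length(donors) == 0) next
    for (j in donors) {
      if (length(donors) == 1) {
        a[g, j] <- y[g, donors]
        next
      }
      h <- bandwidths[g]
      d <- abs(r[j] - r[donors])
      w <- exp(-d^2 / (2 * h^2))
      if (is.finite(cutoff)) w[d > cutoff * h] <- 0
      if (all(w == 0)) { w <- rep(0, length(donors)); w[which.min(d)] <- 1 }
      w <- w / sum(w)
      a[g, j] <- exp(sum(w * log(y[g, donors])))
    }
  }
  m <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    e <- y[g, ][y[g, ] > 0]
    if (length(e)) m[g] <- exp(mean(log(e)))
  }
  theta_raw <- vapply(seq_len(n), function(j) {
    genes <- which(y[, j] > 0)
    median(a[genes, j] / m[genes])
  }, numeric(1))
  list(a = a, m = m, theta_raw = theta_raw,
       theta = theta_raw / exp(mean(log(theta_raw))))
}

# Random sparse-ish count matrix with every cell guaranteed non-empty.
random_counts <- function(G, n, seed = 1, mu = 2, zero_frac = 0.5) {
  set.seed(seed)
  y <- matrix(rpois(G * n, mu), G, n)
  y[runif(G * n) < zero_frac] <- 0L
  for (j in which(colSums(y) == 0)) y[sample(G, 1), j] <- 1L
  rownames(y) <- paste0("g", seq_len(G))
  colnames(y) <- paste0("c", seq_len(n))
  y
}
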