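#' Configuration for a synthetic scRNA-seq dataset
#'
#' Describes one simulated dataset: three subpopulations of cells with known
#' per-cell technical scale factors, known per-gene fold changes, and one of
#' three generative settings that differ in how counts arise from the mean
#' structure \eqn{\mu_{gj} = \mu_g \cdot f_{g,pop(j)} \cdot s_j}:
#' \describe{
#'   \item{I}{log count linear in log depth with additive Gaussian noise on
#'     the log scale, exponentiated and rounded (half-to-even) to integers;}
#'   \item{II}{the same log-linear count-depth mean structure with negative
#'     binomial sampling;}
#'   \item{III}{negative binomial counts with a heavy-tailed gene-mean
#'     distribution and a free cell-specific scale, with no built-in
#'     count-depth relationship.}
#' }
#' Scenario modifiers are applied to the mean structure before sampling:
#' differential expression multiplies the means of a seeded random gene
#' subset by \eqn{2^{lfc}} in subpopulation 2 or 3; `composition_boost`
#' multiplies the means of the top-expressed gene fraction in subpopulation 1
#' (an RNA-composition shift); `dropout_rate` adds independent zero-inflation
#' after sampling, with per-entry retention probability increasing in the
#' mean.
#'
#' @param setting `"I"`, `"II"` or `"III"`.
#' @param n_genes Number of genes (>= 10; default 3000).
#' @param subpop_sizes Integer vector of 3 subpopulation sizes (sum >= 4).
#' @param depth_factors Either a length-2 positive range, sampled
#'   log-uniformly per cell (default `c(0.25, 4)`), or an explicit vector of
#'   per-cell scale factors `s_j` (length `sum(subpop_sizes)`).
#' @param de_fraction Fraction of genes differentially expressed, in
#'   `[0, 1)`. Default 0.1.
#' @param de_log2fc Positive log2 fold change for DE genes: a scalar, or a
#'   length-2 range sampled uniformly per DE gene. Default `c(1, 2.5)`.
#' @param composition_boost Length-2 `c(fraction, multiplier)`: multiply the
#'   means of the top `fraction` most-expressed genes by `multiplier` in
#'   subpopulation 1. Default `c(0, 1)` (off).
#' @param dropout_rate Target mean dropout probability added after sampling,
#'   in `[0, 1)`. Default 0.
#' @param nb_dispersion Negative binomial dispersion `phi`
#'   (variance `mu + phi mu^2`) for settings II/III. Default 0.1.
#' @param noise_sd Standard deviation of the log-scale Gaussian noise in
#'   setting I. Default 0.25.
#' @param seed Integer RNG seed; every sampled quantity derives from it.
#' @return A validated `sckwarn_sim_config` list.
#' @seealso [simulate_counts()], [scenario_grid()]
#' @export
simulation_config <- function(setting = c("I", "II", "III"),
                              n_genes = 3000,
                              subpop_sizes = c(100, 100, 100),
                              depth_factors = c(0.25, 4),
                              de_fraction = 0.1,
                              de_log2fc = c(1, 2.5),
                              composition_boost = c(0, 1),
                              dropout_rate = 0,
                              nb_dispersion = 0.1,
                              noise_sd = 0.25,
                              seed = 1L) {
  setting <- match.arg(setting)
  stopifnot_cfg(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 10)
  subpop_sizes <- as.integer(subpop_sizes)
  stopifnot_cfg(length(subpop_sizes) == 3L, all(subpop_sizes >= 1L),
                sum(subpop_sizes) >= 4L)
  n <- sum(subpop_sizes)
  stopifnot_cfg(is.numeric(depth_factors), all(is.finite(depth_factors)),
                all(depth_factors > 0),
                length(depth_factors) == 2L || length(depth_factors) == n)
  if (length(depth_factors) == 2L)
    stopifnot_cfg(depth_factors[1] <= depth_factors[2])
  stopifnot_cfg(is.numeric(de_fraction), length(de_fraction) == 1L,
                de_fraction >= 0, de_fraction < 1)
  stopifnot_cfg(is.numeric(de_log2fc), length(de_log2fc) %in% 1:2,
                all(de_log2fc > 0))
  if (length(de_log2fc) == 2L) stopifnot_cfg(de_log2fc[1] <= de_log2fc[2])
  stopifnot_cfg(is.numeric(composition_boost), length(composition_boost) == 2L,
                composition_boost[1] >= 0, composition_boost[1] < 1,
                composition_boost[2] > 0)
  stopifnot_cfg(is.numeric(dropout_rate), length(dropout_rate) == 1L,
                dropout_rate >= 0, dropout_rate < 1)
  stopifnot_cfg(is.numeric(nb_dispersion), length(nb_dispersion) == 1L,
                nb_dispersion > 0)
  stopifnot_cfg(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  stopifnot_cfg(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(setting = setting, n_genes = as.integer(n_genes),
                 subpop_sizes = subpop_sizes, depth_factors = depth_factors,
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 composition_boost = composition_boost,
                 dropout_rate = dropout_rate, nb_dispersion = nb_dispersion,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sckwarn_sim_config")
}

stopifnot_cfg <- function(...) {
  ok <- vapply(list(...), isTRUE, logical(1))
  if (!all(ok)) {
    calls <- vapply(substitute(list(...))[-1L], deparse1, character(1))
    stop("invalid simulation config: ", paste(calls[!ok], collapse = "; "),
         call. = FALSE)
  }
}

#' Simulate a count matrix with known ground truth
#'
#' Draws one dataset from a [simulation_config()]: gene base means, per-cell
#' scale factors, fold-change assignments and counts, all from the config's
#' seed (bit-reproducible; the caller's RNG state is untouched). The returned
#' truth is exactly the mean multiplier injected: non-DE genes have log2 fold
#' change 0 exactly, and DE/boosted multipliers are recoverable from
#' `true_log2fc` with no hidden rescaling.
#'
#' @param config A `sckwarn_sim_config`.
#' @return An object of class `sckwarn_sim`: a list with `counts` (sparse
#'   genes-by-cells integer matrix), `labels` (per-cell subpopulation 1-3),
#'   `true_log2fc` (genes x 2 matrix, contrasts pop2-vs-pop1 and
#'   pop3-vs-pop1), `true_scale` (per-cell `s_j`), and `config`.
#' @examples
#' sim <- simulate_counts(simulation_config("III", n_genes = 200,
#'                                          subpop_sizes = c(20, 20, 20)))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sckwarn_sim_config"))
    stop("'config' must come from simulation_config()", call. = FALSE)
  cfg <- config
  G <- cfg$n_genes
  n <- sum(cfg$subpop_sizes)
  pop <- rep.int(1:3, cfg$subpop_sizes)

  with_seed(cfg$seed, {
    s <- if (length(cfg$depth_factors) == 2L)
      exp(runif(n, log(cfg$depth_factors[1]), log(cfg$depth_factors[2])))
    else cfg$depth_factors

    mu <- if (cfg$setting == "III")
      rlnorm(G, meanlog = 0, sdlog = 1.8)     # heavy-tailed base means
    else
      rlnorm(G, meanlog = 0.5, sdlog = 1.2)

    fc <- matrix(1, G, 3L)
    n_de <- round(cfg$de_fraction * G)
    if (n_de > 0) {
      de_idx <- sample.int(G, n_de)
      de_pop <- sample(2:3, n_de, replace = TRUE)
      lfc <- if (length(cfg$de_log2fc) == 1L) rep(cfg$de_log2fc, n_de)
             else runif(n_de, cfg$de_log2fc[1], cfg$de_log2fc[2])
      fc[cbind(de_idx, de_pop)] <- 2^lfc
    }
    if (cfg$composition_boost[1] > 0 && cfg$composition_boost[2] != 1) {
      ntop <- ceiling(cfg$composition_boost[1] * G)
      top <- order(mu, decreasing = TRUE)[seq_len(ntop)]
      fc[top, 1L] <- fc[top, 1L] * cfg$composition_boost[2]
    }

    M <- sweep(mu * fc[, pop, drop = FALSE], 2L, s, "*")  # mean mu_g*f_gp*s_j
    y <- if (cfg$setting == "I")
      round(exp(log(M) + rnorm(G * n, 0, cfg$noise_sd)))
    else
      matrix(rnbinom(G * n, mu = M, size = 1 / cfg$nb_dispersion), G, n)

    if (cfg$dropout_rate > 0) {
      lam <- dropout_lambda(M, cfg$dropout_rate)
      keep <- matrix(rbinom(G * n, 1L, 1 - exp(-lam * M)), G, n)
      y <- y * keep
    }
  })

  dimnames(y) <- list(sprintf("gene%04d", seq_len(G)),
                      sprintf("cell%04d", seq_len(n)))
  counts <- methods::as(methods::as(Matrix::Matrix(y, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  truth <- cbind(pop2_vs_pop1 = log2(fc[, 2L] / fc[, 1L]),
                 pop3_vs_pop1 = log2(fc[, 3L] / fc[, 1L]))
  rownames(truth) <- rownames(counts)
  structure(list(counts = counts, labels = pop, true_log2fc = truth,
                 true_scale = stats::setNames(s, colnames(counts)),
                 config = cfg),
            class = "sckwarn_sim")
}

# Zero-inflation intensity: solve mean(exp(-lambda * M)) = target over all
# entries, so the average added dropout probability hits the requested rate.
dropout_lambda <- function(M, target) {
  f <- function(u) mean(exp(-10^u * M)) - target
  10^uniroot(f, c(-12, 8), tol = 1e-10)$root
}

#' The five benchmark scenario configurations
#'
#' Returns the five scenario configurations used throughout the benchmarks,
#' each altering one dimension of a common baseline (plus the DE level for
#' scenario 5): wider library-size spread, an RNA-composition shift from
#' boosted top genes, added dropout, unbalanced subpopulation sizes (10:1:1),
#' and unbalanced sizes combined with strong DE (25% of genes, log2 fold
#' changes 2-4). Each scenario carries a distinct deterministic seed; two
#' calls with the same arguments return identical configurations.
#'
#' @param setting `"I"`, `"II"` or `"III"`.
#' @param n_genes,subpop_sizes Baseline dimensions (defaults 3000 and
#'   `c(100, 100, 100)`); the unbalanced scenarios re-split the same total.
#' @param base_seed Integer offset folded into each scenario's seed.
#' @return Named list of 5 `sckwarn_sim_config` objects.
#' @export
scenario_grid <- function(setting = c("I", "II", "III"), n_genes = 3000,
                          subpop_sizes = c(100, 100, 100), base_seed = 0L) {
  setting <- match.arg(setting)
  si <- match(setting, c("I", "II", "III"))
  tot <- sum(subpop_sizes)
  unbal <- c(tot - 2L * max(2L, round(tot / 12)),
             max(2L, round(tot / 12)), max(2L, round(tot / 12)))
  mk <- function(i, ...)
    simulation_config(setting, n_genes = n_genes, subpop_sizes = subpop_sizes,
                      seed = base_seed + 1000L * si + i, ...)
  list(
    library_size = mk(1L, depth_factors = c(0.1, 10)),
    rna_composition = mk(2L, composition_boost = c(0.02, 5)),
    dropout = mk(3L, dropout_rate = 0.2),
    cell_composition =
      simulation_config(setting, n_genes = n_genes, subpop_sizes = unbal,
                        seed = base_seed + 1000L * si + 4L),
    composition_strong_de =
      simulation_config(setting, n_genes = n_genes, subpop_sizes = unbal,
                        de_fraction = 0.25, de_log2fc = c(2, 4),
                        seed = base_seed + 1000L * si + 5L)
  )
}
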