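#' Estimate per-gene log2 fold changes between two groups
#'
#' Ratio-of-means estimator on normalized expression with a pseudocount:
#' `log2((mean in group A + pc) / (mean in group B + pc))`. The pseudocount
#' guards against zero means; its distortion vanishes as counts grow.
#'
#' @param normalized Genes-by-cells normalized expression matrix.
#' @param labels Per-cell group labels.
#' @param contrast Length-2 vector `c(A, B)`: fold changes of group A over
#'   group B. Each group must contain >= 2 cells.
#' @param pseudocount Added to both group means (default 1).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
estimate_log2fc <- function(normalized, labels, contrast, pseudocount = 1) {
  stopifnot(length(labels) == ncol(normalized), length(contrast) == 2L)
  ia <- which(labels == contrast[1L]); ib <- which(labels == contrast[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each contrast group needs >= 2 cells", call. = FALSE)
  ma <- Matrix::rowMeans(normalized[, ia, drop = FALSE])
  mb <- Matrix::rowMeans(normalized[, ib, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  names(lfc) <- rownames(normalized)
  lfc
}

#' Bias and root mean square error of fold-change estimates
#'
#' `bias = mean(estimated - truth)` and `rmse = sqrt(mean((estimated -
#' truth)^2))` over a gene subset (all genes by default). RMSE also reflects
#' the variance of the error, not just its average.
#'
#' @param estimated,truth Equal-length numeric vectors of log2 fold changes.
#' @param subset Optional logical or integer subset of genes (default: all).
#' @return List with `bias` and `rmse`.
#' @export
bias_rmse <- function(estimated, truth, subset = NULL) {
  if (length(estimated) != length(truth))
    stop("'estimated' and 'truth' must have equal length", call. = FALSE)
  if (!is.null(subset)) {
    estimated <- estimated[subset]; truth <- truth[subset]
  }
  if (length(estimated) == 0L) stop("empty gene subset", call. = FALSE)
  d <- estimated - truth
  list(bias = mean(d), rmse = sqrt(mean(d^2)))
}

#' Call differentially expressed genes between two groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on `log1p`-normalized
#' expression, Benjamini-Hochberg adjusted, called at adjusted p < `alpha`.
#' Genes expressed (non-zero) in fewer than 3 cells across the two groups are
#' not tested and are called negative. A fully tied gene (identical values in
#' both groups) is assigned p = 1.
#'
#' @param normalized Genes-by-cells normalized expression matrix.
#' @param labels Per-cell group labels.
#' @param contrast Length-2 vector of the two group labels; each group must
#'   contain >= 3 cells.
#' @param alpha Adjusted-p call threshold (default 0.05).
#' @return data.frame with columns `gene_id`, `tested`, `p_value`,
#'   `p_adjusted`, `called`.
#' @export
call_de <- function(normalized, labels, contrast, alpha = 0.05) {
  stopifnot(length(labels) == ncol(normalized), length(contrast) == 2L)
  ia <- which(labels == contrast[1L]); ib <- which(labels == contrast[2L])
  if (length(ia) < 3L || length(ib) < 3L)
    stop("each contrast group needs >= 3 cells", call. = FALSE)
  sub <- as.matrix(normalized[, c(ia, ib), drop = FALSE])
  ga <- seq_along(ia); gb <- length(ia) + seq_along(ib)
  tested <- rowSums(sub > 0) >= 3L
  p <- rep(NA_real_, nrow(sub))
  L <- log1p(sub)
  for (g in which(tested)) {
    pv <- suppressWarnings(
      wilcox.test(L[g, ga], L[g, gb], exact = FALSE)$p.value)
    p[g] <- if (is.finite(pv)) pv else 1
  }
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(gene_id = rownames(normalized) %||% as.character(seq_len(nrow(sub))),
             tested = tested,
             p_value = p,
             p_adjusted = padj,
             called = !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE)
}

#' Sensitivity, specificity and F1 of DE calls against truth
#'
#' Standard confusion-matrix summaries. Empty-denominator cases (no true
#' positives in the truth, no calls, etc.) return 0 for the affected metric
#' and are listed in the `flagged` element.
#'
#' @param calls,truth Equal-length logical vectors.
#' @return List with `sensitivity`, `specificity`, `f1`, the confusion counts
#'   `tp`/`fp`/`fn`/`tn`, and `flagged` (character vector of metrics whose
#'   denominator was empty).
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' must have equal length", call. = FALSE)
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  flagged <- character(0)
  sens <- if (tp + fn == 0L) { flagged <- c(flagged, "sensitivity"); 0 } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) { flagged <- c(flagged, "specificity"); 0 } else tn / (tn + fp)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) { flagged <- c(flagged, "f1"); 0 } else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn, flagged = flagged)
}

#' Residual depth-bias score of a normalized matrix
#'
#' One minus the maximum absolute Pearson correlation between per-cell
#' sequencing depths and the first two principal components of
#' `log1p`-normalized expression (cells as observations). A score near 1
#' means the leading expression structure is uncorrelated with depth, i.e.
#' the normalization removed the depth confounder. A zero-variance principal
#' component, or a constant depth vector, contributes correlation 0 (the
#' result then carries attribute `flagged = TRUE`).
#'
#' @param normalized Genes-by-cells normalized expression matrix (n >= 3
#'   cells).
#' @param depths Per-cell sequencing depths (e.g. raw column sums).
#' @return Scalar in `[0, 1]`.
#' @export
depth_correlation_score <- function(normalized, depths) {
  n <- ncol(normalized)
  if (n < 3L) stop("need >= 3 cells", call. = FALSE)
  if (length(depths) != n)
    stop("'depths' must have one value per cell", call. = FALSE)
  L <- log1p(Matrix::t(normalized))       # cells x genes
  pc <- prcomp(as.matrix(L), center = TRUE, scale. = FALSE, rank. = 2L)
  flagged <- FALSE
  cors <- vapply(seq_len(min(2L, ncol(pc$x))), function(k) {
    sc <- pc$x[, k]
    if (sd(sc) == 0 || sd(depths) == 0) { flagged <<- TRUE; return(0) }
    abs(cor(sc, depths))
  }, numeric(1))
  structure(1 - max(cors, 0), flagged = flagged)
}

#' Evaluate one normalization run against simulation ground truth
#'
#' Computes the full metric panel for one simulated dataset and one vector of
#' size factors: fold-change bias and RMSE against the injected truth, DE
#' sensitivity/specificity/F1 (Wilcoxon + BH calls), the residual
#' depth-correlation score, and the size-factor recovery correlation
#' `cor(log theta, log s_true)`.
#'
#' @param sim A `sckwarn_sim` from [simulate_counts()].
#' @param theta Per-cell size factors to evaluate.
#' @param contrast Length-2 subpopulation contrast `c(A, B)` (default
#'   `c(2, 1)`, matching the stored truth column `pop2_vs_pop1`).
#' @param alpha DE call threshold.
#' @param subset Optional gene subset for bias/RMSE (default: all genes).
#' @return One-row data.frame: `bias`, `rmse`, `sensitivity`, `specificity`,
#'   `f1`, `depth_corr_score`, `n_de_called`, `sf_log_cor`.
#' @export
evaluate_normalization <- function(sim, theta, contrast = c(2, 1),
                                   alpha = 0.05, subset = NULL) {
  if (!inherits(sim, "sckwarn_sim"))
    stop("'sim' must come from simulate_counts()", call. = FALSE)
  norm <- normalize_counts(sim$counts, theta)
  truth_col <- sprintf("pop%d_vs_pop%d", contrast[1L], contrast[2L])
  if (!truth_col %in% colnames(sim$true_log2fc))
    stop(sprintf("no stored truth for contrast %s", truth_col), call. = FALSE)
  truth <- sim$true_log2fc[, truth_col]
  est <- estimate_log2fc(norm, sim$labels, contrast)
  br <- bias_rmse(est, truth, subset)
  de <- call_de(norm, sim$labels, contrast, alpha = alpha)
  cm <- confusion_metrics(de$called, truth != 0)
  dscore <- depth_correlation_score(norm, Matrix::colSums(sim$counts))
  data.frame(bias = br$bias, rmse = br$rmse,
             sensitivity = cm$sensitivity, specificity = cm$specificity,
             f1 = cm$f1,
             depth_corr_score = as.numeric(dscore),
             n_de_called = sum(de$called),
             sf_log_cor = cor(log(theta), log(sim$true_scale)))
}

#' Run the simulation benchmark grid
#'
#' For every combination of setting, scenario, replicate and method:
#' simulate, normalize, evaluate; one tidy row per combination. Methods are
#' `"sckwarn"` (this package's kernel-weighted normalization) and
#' `"relative_counts"` (library-size scaling rescaled to geometric mean 1).
#' All seeds derive deterministically from `base_seed`, so the same call
#' returns an identical table.
#'
#' @param settings Subset of `c("I", "II", "III")`.
#' @param scenarios Subset of the [scenario_grid()] names (default: all 5).
#' @param replicates Replicate datasets per grid cell (default 20; the
#'   full-scale convention in this literature is 100).
#' @param methods Subset of `c("sckwarn", "relative_counts")`.
#' @param n_genes,subpop_sizes Passed to [scenario_grid()].
#' @param base_seed Integer master seed.
#' @param cutoff Kernel cutoff passed to [sckwarn()].
#' @param alpha DE call threshold.
#' @return data.frame with columns `setting`, `scenario`, `replicate`,
#'   `method`, `seed`, and the [evaluate_normalization()] metric columns.
#' @export
run_benchmark <- function(settings = c("I", "II", "III"), scenarios = NULL,
                          replicates = 20L,
                          methods = c("sckwarn", "relative_counts"),
                          n_genes = 3000, subpop_sizes = c(100, 100, 100),
                          base_seed = 1L, cutoff = 2, alpha = 0.05) {
  settings <- match.arg(settings, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  all_scen <- names(scenario_grid("I", n_genes = 10, subpop_sizes = c(2, 2, 2)))
  scenarios <- scenarios %||% all_scen
  if (!all(scenarios %in% all_scen))
    stop("unknown scenario(s): ", paste(setdiff(scenarios, all_scen), collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (set in settings) {
    for (scen in scenarios) {
      for (rep_i in seq_len(replicates)) {
        grid <- scenario_grid(set, n_genes = n_genes,
                              subpop_sizes = subpop_sizes,
                              base_seed = base_seed + 20000L * rep_i)
        cfg <- grid[[scen]]
        cell <- sprintf("setting %s / scenario %s / replicate %d", set, scen, rep_i)
        res <- tryCatch({
          sim <- simulate_counts(cfg)
          do.call(rbind, lapply(methods, function(mth) {
            theta <- switch(mth,
                            sckwarn = sckwarn(sim$counts, cutoff = cutoff)$theta,
                            relative_counts = relative_counts(sim$counts))
            cbind(data.frame(setting = set, scenario = scen,
                             replicate = rep_i, method = mth,
                             seed = cfg$seed, stringsAsFactors = FALSE),
                  evaluate_normalization(sim, theta, alpha = alpha))
          }))
        }, error = function(e) {
          stop(sprintf("benchmark failed at %s: %s", cell, conditionMessage(e)),
               call. = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
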