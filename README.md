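# sckwarn

Kernel-weighted-average robust normalization for single-cell RNA-seq count
matrices.

## What problem this solves

Raw scRNA-seq counts confound biology with cell-level technical effects:
sequencing depth, capture efficiency, amplification bias, dropout.
Normalization divides each cell's counts by a size factor θ_j that absorbs
these effects. Most estimators model the count-depth relationship or assume
a parametric count distribution; when those assumptions fail (cell-type
specific count-depth slopes, hidden confounders beyond depth), factors are
over- or under-corrected. `sckwarn` estimates per-cell **global** size
factors without either assumption, for analysts who need depth- and
composition-robust scaling before downstream DE or clustering work.

## The estimator

With counts y_gj, non-zero gene sets R_j = {g : y_gj > 0} and expressing
cell sets C_g = {j : y_gj > 0}:

1. **Technical axis** — r = PC1 of the n×3 matrix of per-cell 25th/50th/75th
   percentiles of log non-zero counts; |r_j − r_j′| measures technical
   similarity.
2. **Pseudo-profiles** — a_gj = exp( Σ_{j′∈C_g} w_g,(j,j′) log y_gj′ ), a
   kernel-weighted geometric mean over the gene's expressing cells, with
   Gaussian weights w ∝ exp(−(r_j − r_j′)²/2h_g²) and gene-specific
   Sheather–Jones bandwidths h_g.
3. **References** — m_g = geometric mean of gene g's non-zero counts; each
   cell is compared only on its own expressed genes, keeping the non-DE
   assumption valid under unbalanced populations.
4. **Median ratio** — θ_j = median{ a_gj / m_g : g ∈ R_j }, rescaled to
   geometric mean 1.

The package also ships a ground-truth count simulator (three generative
settings × five distortion scenarios) and an evaluation suite (bias, RMSE,
sensitivity/specificity/F1 of Wilcoxon+BH DE calls, residual
depth-correlation score, size-factor recovery) for benchmarking
normalizations on synthetic data. See the vignette in `vignettes/` for the
full model account and every default.

## Worked example

```r
library(sckwarn)
sim <- simulate_counts(simulation_config("III", n_genes = 1000,
                                         subpop_sizes = c(60, 60, 60),
                                         seed = 7))
fit <- sckwarn(sim$counts)
print(fit)
#> sckwarn normalization: 180 cells, 1000 genes
#>   cutoff: 2; rescaling: geometric_mean_1
#>   technical axis PC1 variance fraction: 0.924
#>   bandwidths: none=996, silverman=1, single=3
#>   size factors:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.3987  0.6324  1.0249  1.1477  1.6018  2.6064
```

Reading this: the first principal component of the quantile summaries
carries 92% of their variance, so the single technical axis is an adequate
neighbor coordinate; 996 of 1000 genes got a data-driven Sheather–Jones
bandwidth (1 fell back to Silverman's rule, 3 are expressed in a single
cell); the factors span the simulated depth range. Because this simulation
carries known truth, we can check recovery:

```r
cor(log(fit$theta), log(sim$true_scale))
#> [1] 0.9870893
round(head(fit$theta, 4), 4)
#> cell0001 cell0002 cell0003 cell0004
#>   2.4541   0.7582   0.4621   0.4675
```

Normalized expression is `y[, j] / theta[j]`:

```r
norm <- normalize_counts(sim$counts, fit$theta)
```

A thin command-line front end over the same functions lives at
`inst/scripts/sckwarn` (`normalize`, `simulate`, `benchmark` subcommands;
`--help` documents every default).

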