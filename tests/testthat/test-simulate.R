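test_that("configs validate their fields before any sampling", {
  expect_s3_class(simulation_config("I"), "sckwarn_sim_config")
  expect_error(simulation_config("I", n_genes = 5), "invalid simulation config")
  expect_error(simulation_config("I", subpop_sizes = c(1, 1, 1)), "invalid")
  expect_error(simulation_config("I", de_fraction = 1), "invalid")
  expect_error(simulation_config("I", depth_factors = c(2, 1)), "invalid")
  expect_error(simulation_config("I", dropout_rate = -0.1), "invalid")
  expect_error(simulation_config("bogus"), "arg")
})

test_that("simulation is bit-reproducible and leaves the caller's RNG alone", {
  cfg <- simulation_config("II", n_genes = 100, subpop_sizes = c(10, 10, 10),
                           seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  s1 <- simulate_counts(cfg)
  after <- runif(1)
  expect_identical(before, after)  # RNG state restored around simulation
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$true_scale, s2$true_scale)
  expect_identical(s1$true_log2fc, s2$true_log2fc)
})

test_that("ground truth is exact: non-DE genes have zero log2fc", {
  cfg0 <- simulation_config("III", n_genes = 200, subpop_sizes = c(10, 10, 10),
                            de_fraction = 0, seed = 7)
  s0 <- simulate_counts(cfg0)
  expect_true(all(s0$true_log2fc == 0))

  cfg <- simulation_config("III", n_genes = 200, subpop_sizes = c(10, 10, 10),
                           de_fraction = 0.2, de_log2fc = 2, seed = 7)
  s <- simulate_counts(cfg)
  n_de <- sum(rowSums(s$true_log2fc != 0) > 0)
  expect_equal(n_de, 40)
  hit <- s$true_log2fc[s$true_log2fc != 0]
  expect_true(all(hit == 2))  # scalar lfc injected verbatim
})

test_that("labels, scales and dimensions line up with the config", {
  cfg <- simulation_config("I", n_genes = 50, subpop_sizes = c(4, 6, 8),
                           seed = 3)
  s <- simulate_counts(cfg)
  expect_identical(dim(s$counts), c(50L, 18L))
  expect_identical(s$labels, rep(1:3, c(4, 6, 8)))
  expect_length(s$true_scale, 18)
  expect_true(all(s$counts@x >= 0 & s$counts@x == round(s$counts@x)))
})

test_that("setting I with no variation gives identical cells and unit factors", {
  cfg <- simulation_config("I", n_genes = 60, subpop_sizes = c(4, 4, 4),
                           depth_factors = rep(1, 12), de_fraction = 0,
                           noise_sd = 0, seed = 5)
  s <- simulate_counts(cfg)
  expect_true(all(s$counts[, 1] == s$counts))
  expect_identical(unname(sckwarn(s$counts)$theta), rep(1, 12))
})

test_that("library size tracks the true scale in the depth-coupled settings", {
  for (set in c("I", "II")) {
    cfg <- simulation_config(set, n_genes = 400, subpop_sizes = c(30, 30, 30),
                             seed = 17)
    s <- simulate_counts(cfg)
    expect_gt(cor(s$true_scale, Matrix::colSums(s$counts), method = "spearman"),
              0.8)
  }
})

# Redraw the generator's gene means for the coverage check below: the
# generator draws depth factors first (n uniforms), then gene means.
with_seed_draws <- function(cfg) {
  n <- sum(cfg$subpop_sizes)
  set.seed(cfg$seed)
  runif(n)
  rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.8)
}

test_that("NB means match the injected mean structure (setting III)", {
  # no DE, dispersion small: per-gene empirical means across cells should
  # straddle the s-weighted theoretical mean mu_g * mean(s)
  cfg <- simulation_config("III", n_genes = 2000, subpop_sizes = c(200, 200, 200),
                           de_fraction = 0, nb_dispersion = 0.05, seed = 23)
  s <- simulate_counts(cfg)
  emp <- Matrix::rowMeans(s$counts)
  # reconstruct mu_g from the config seed exactly as the generator draws it
  mu <- with_seed_draws(cfg)
  n <- ncol(s$counts)
  theo <- mu * mean(s$true_scale)
  se <- sqrt((theo + cfg$nb_dispersion * mu^2 * mean(s$true_scale^2)) / n)
  cover <- mean(abs(emp - theo) <= 3 * pmax(se, 1e-12))
  expect_gt(cover, 0.95)
})

test_that("dropout monotonically increases the zero fraction", {
  zf <- vapply(c(0, 0.15, 0.3), function(d) {
    cfg <- simulation_config("II", n_genes = 300, subpop_sizes = c(20, 20, 20),
                             dropout_rate = d, seed = 29)
    s <- simulate_counts(cfg)
    mean(as.matrix(s$counts) == 0)
  }, numeric(1))
  expect_true(all(diff(zf) > 0))
})

test_that("scenario grid alters exactly the documented dimension", {
  for (set in c("I", "III")) {
    grid <- scenario_grid(set, n_genes = 100, subpop_sizes = c(10, 10, 10))
    base <- simulation_config(set, n_genes = 100, subpop_sizes = c(10, 10, 10))
    expect_named(grid, c("library_size", "rna_composition", "dropout",
                         "cell_composition", "composition_strong_de"))
    differs <- function(cfg, base) {
      flds <- setdiff(names(base), "seed")
      flds[!vapply(flds, function(f) identical(cfg[[f]], base[[f]]), logical(1))]
    }
    expect_identical(differs(grid$library_size, base), "depth_factors")
    expect_identical(differs(grid$rna_composition, base), "composition_boost")
    expect_identical(differs(grid$dropout, base), "dropout_rate")
    expect_identical(differs(grid$cell_composition, base), "subpop_sizes")
    expect_setequal(differs(grid$composition_strong_de, base),
                    c("subpop_sizes", "de_fraction", "de_log2fc"))
    # unbalanced composition: 10:1 ratio between largest and smallest
    expect_gte(max(grid$cell_composition$subpop_sizes) /
                 min(grid$cell_composition$subpop_sizes), 10)
    # seeds distinct, calls deterministic
    seeds <- vapply(grid, `[[`, integer(1), "seed")
    expect_length(unique(seeds), 5)
    expect_identical(grid, scenario_grid(set, n_genes = 100,
                                         subpop_sizes = c(10, 10, 10)))
  }
})
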