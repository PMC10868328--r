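test_that("log2 fold-change estimator: ratio construction and pseudocount", {
  labels <- rep(c("A", "B"), each = 4)
  # A mean 3, B mean 1, pseudocount 1 -> log2(4/2) = 1
  m <- rbind(g1 = c(rep(3, 4), rep(1, 4)))
  expect_equal(unname(estimate_log2fc(m, labels, c("A", "B"))), 1)
  # identical groups -> exactly 0
  m2 <- rbind(g1 = rep(5, 8), g2 = rep(0, 8))
  expect_equal(unname(estimate_log2fc(m2, labels, c("A", "B"))), c(0, 0))
  # 2x ratio converges to 1 as counts grow
  m3 <- rbind(g1 = c(rep(400, 4), rep(200, 4)))
  expect_equal(unname(estimate_log2fc(m3, labels, c("A", "B"))), 1,
               tolerance = 0.01)
  expect_error(estimate_log2fc(m, labels, c("A", "C")), ">= 2 cells")
})

test_that("bias and RMSE follow their definitions", {
  expect_equal(bias_rmse(1:5, 1:5), list(bias = 0, rmse = 0))
  expect_equal(bias_rmse(1:5 + 0.3, 1:5), list(bias = 0.3, rmse = 0.3))
  expect_equal(bias_rmse(c(-1, 1), c(0, 0)), list(bias = 0, rmse = 1))
  d <- rnorm(20)
  br <- bias_rmse(d, rep(0, 20))
  expect_gte(br$rmse^2, br$bias^2)          # rmse^2 >= bias^2 always
  expect_error(bias_rmse(1:3, 1:4), "equal length")
  expect_error(bias_rmse(1:3, 1:3, subset = integer(0)), "empty")
})

test_that("DE calling: ties give no calls, disjoint supports are called", {
  labels <- rep(c("A", "B"), each = 10)
  # identical groups: everything tied -> p 1 -> zero calls
  m <- matrix(rep(c(2, 0, 7), 20), nrow = 3, dimnames = list(paste0("g", 1:3), NULL))
  de <- call_de(m, labels, c("A", "B"))
  expect_equal(sum(de$called), 0)
  expect_true(all(de$p_value[de$tested] == 1))

  # one gene with disjoint supports (all A > all B): rank-sum tail is far
  # below 0.05, so the gene is called when tested alone
  m2 <- rbind(g1 = c(11:20, 1:10))
  de2 <- call_de(m2, labels, c("A", "B"))
  expect_true(de2$called[1])
  # cross-check against the exact rank-sum tail
  p_exact <- wilcox.test(11:20, 1:10, exact = TRUE)$p.value
  expect_lt(p_exact, 0.05)

  # genes expressed in < 3 cells are not tested and called negative
  m3 <- rbind(g1 = c(11:20, 1:10), g2 = c(1, rep(0, 18), 2))
  de3 <- call_de(m3, labels, c("A", "B"))
  expect_false(de3$tested[2])
  expect_false(de3$called[2])
  expect_error(call_de(m2, rep(c("A", "B"), c(2, 18)), c("A", "B")), ">= 3")
})

test_that("type-I error of the Wilcoxon+BH caller is controlled on null data", {
  # 500 null genes x 20 replicates at alpha 0.05 on *unadjusted* p-values:
  # false-positive proportion within binomial noise of alpha
  set.seed(333)
  labels <- rep(c("A", "B"), each = 10)
  fp <- 0; tot <- 0
  for (rep_i in 1:20) {
    m <- matrix(rpois(25 * 20, 5), nrow = 25)
    de <- call_de(m, labels, c("A", "B"))
    fp <- fp + sum(de$p_value[de$tested] < 0.05, na.rm = TRUE)
    tot <- tot + sum(de$tested)
  }
  se <- sqrt(0.05 * 0.95 / tot)
  expect_lte(fp / tot, 0.05 + 2 * se)
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(17)
  labels <- rep(c("A", "B"), each = 6)
  m <- matrix(rpois(50 * 12, 4), nrow = 50)
  m[1:5, labels == "A"] <- m[1:5, labels == "A"] + 20L
  de <- call_de(m, labels, c("A", "B"))
  ok <- de$tested
  o <- order(de$p_value[ok])
  expect_true(all(diff(de$p_adjusted[ok][o]) >= -1e-12))
})

test_that("confusion metrics handle mixed and degenerate cases", {
  calls <- c(rep(TRUE, 10), rep(FALSE, 90))
  truth <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 2), rep(FALSE, 88))
  cm <- confusion_metrics(calls, truth)
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$specificity, 88 / 90)
  expect_equal(cm$f1, 0.8)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$f1),
               c(1, 1, 1))

  none <- confusion_metrics(rep(FALSE, 10), rep(FALSE, 10))
  expect_equal(none$specificity, 1)
  expect_equal(none$sensitivity, 0)
  expect_true("sensitivity" %in% none$flagged)
})

test_that("depth-correlation score detects a constructed confound", {
  set.seed(55)
  depths <- exp(rnorm(100, sd = 0.4))
  # expression variation purely proportional to depth -> score near 0
  base <- matrix(rpois(50 * 100, 20), 50, 100)
  confounded <- round(sweep(base, 2, depths, "*"))
  expect_lt(depth_correlation_score(confounded, depths), 0.15)
  # expression independent of depth -> high score
  indep <- matrix(rpois(50 * 100, 20), 50, 100)
  expect_gt(depth_correlation_score(indep, depths), 0.7)
  # constant depth vector: correlations undefined -> treated as 0, flagged
  s <- depth_correlation_score(indep, rep(5, 100))
  expect_equal(as.numeric(s), 1)
  expect_true(attr(s, "flagged"))
})

test_that("self-evaluation of truth yields bias 0, rmse 0, f1 1", {
  truth <- c(rep(1.5, 10), rep(0, 40))
  br <- bias_rmse(truth, truth)
  expect_equal(c(br$bias, br$rmse), c(0, 0))
  cm <- confusion_metrics(truth != 0, truth != 0)
  expect_equal(cm$f1, 1)
})

test_that("benchmark rows are deterministic, complete and in range", {
  tab <- run_benchmark(settings = "III", scenarios = "library_size",
                       replicates = 1, n_genes = 150,
                       subpop_sizes = c(8, 8, 8), base_seed = 5)
  tab2 <- run_benchmark(settings = "III", scenarios = "library_size",
                        replicates = 1, n_genes = 150,
                        subpop_sizes = c(8, 8, 8), base_seed = 5)
  expect_identical(tab, tab2)
  expect_setequal(tab$method, c("sckwarn", "relative_counts"))
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_true(all(tab$specificity >= 0 & tab$specificity <= 1))
  expect_true(all(tab$depth_corr_score >= 0 & tab$depth_corr_score <= 1))
  expect_true(all(tab$rmse >= 0))
  expect_error(run_benchmark(scenarios = "nope", replicates = 1), "unknown scenario")
})
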