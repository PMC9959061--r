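test_that("summarize_groups computes mean, SEM and batch counts", {
  out <- summarize_groups(c(2, 4, 6), rep("A", 3), c("b1", "b1", "b2"))
  expect_equal(out$mean, 4)
  expect_equal(out$sem, 2 / sqrt(3))   # sample SD 2
  expect_identical(out$n_larvae, 3L)
  expect_identical(out$n_batches, 2L)

  out2 <- summarize_groups(c(5, 3, 3, 3, 3), c("S", "T", "T", "T", "T"))
  expect_true(is.na(out2$sem[out2$treatment == "S"]))
  expect_equal(out2$sem[out2$treatment == "T"], 0)
})

test_that("star codes follow the 0.05 / 0.01 / 0.001 convention", {
  expect_identical(star_code(c(0.2, 0.049, 0.0099, 0.0009, NA)),
                   c("ns", "*", "**", "***", NA))
})

test_that("Kruskal-Wallis H and Dunn z match a hand rank computation", {
  # pooled ranks of {1,2,3 | 4,5,6}: R1 = 6, R2 = 15, no ties
  # H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 3.857142857...
  t <- kruskal_dunn(c(1, 2, 3, 4, 5, 6),
                    rep(c("DMSO", "T"), each = 3), "DMSO")
  expect_equal(t$global_stat, 3.857142857142857, tolerance = 1e-12)
  expect_equal(t$global_p, stats::pchisq(3.857142857142857, 1,
                                         lower.tail = FALSE))
  # Dunn z = (5 - 2) / sqrt(42/12 * (1/3 + 1/3))
  expect_equal(t$comparisons$statistic,
               3 / sqrt(42 / 12 * 2 / 3), tolerance = 1e-12)
  expect_equal(t$comparisons$p_adj, t$comparisons$p_raw)  # one comparison

  # identical groups collapse to the null path
  t0 <- kruskal_dunn(rep(5, 8), rep(c("DMSO", "T"), each = 4), "DMSO")
  expect_equal(t0$global_stat, 0)
  expect_equal(t0$comparisons$p_adj, 1)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  withr::local_seed(41)
  v <- rnorm(30)
  g <- rep(c("DMSO", "A", "B"), each = 10)
  t1 <- kruskal_dunn(v, g, "DMSO")
  t2 <- kruskal_dunn(exp(2 * v) + 7, g, "DMSO")
  expect_equal(t1$global_stat, t2$global_stat, tolerance = 1e-12)
  expect_equal(t1$comparisons$p_adj, t2$comparisons$p_adj, tolerance = 1e-12)
})

test_that("Bonferroni-adjusted Dunn p-values never drop below raw ones", {
  withr::local_seed(42)
  v <- rnorm(40)
  g <- rep(c("DMSO", "A", "B", "C"), each = 10)
  t <- kruskal_dunn(v, g, "DMSO")
  expect_identical(nrow(t$comparisons), 3L)
  expect_true(all(t$comparisons$p_adj >= t$comparisons$p_raw))
  expect_true(all(t$comparisons$p_adj <= 1))
  tall <- kruskal_dunn(v, g, "DMSO", all_pairs = TRUE)
  expect_identical(nrow(tall$comparisons), 6L)
})

test_that("one-way ANOVA F matches the hand-computed mean-square ratio", {
  # groups {1,2,3}, {2,3,4}, {6,7,8}: MSB = 21, MSW = 1 -> F = 21
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("DMSO", "A", "B"), each = 3)
  t <- anova_dunnett(v, g, "DMSO")
  expect_equal(t$global_stat, 21, tolerance = 1e-12)
  expect_equal(t$global_p, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(sort(t$comparisons$group), c("A", "B"))
  expect_true(all(t$comparisons$p_adj >= t$comparisons$p_raw - 1e-12))

  t0 <- anova_dunnett(rep(2, 9), g, "DMSO")
  expect_equal(t0$global_stat, 0)
  expect_equal(t0$global_p, 1)

  # distinct constant groups: between-group signal, zero within variance
  expect_error(anova_dunnett(c(1, 1, 1, 2, 2, 2), rep(c("DMSO", "A"), each = 3)),
               class = "staz_degenerate_variance_error")
})

test_that("Dunnett adjustment agrees with the multivariate-t reference", {
  withr::local_seed(43)
  v <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 0.2))
  g <- rep(c("DMSO", "A", "B"), each = 10)
  t <- anova_dunnett(v, g, "DMSO")
  # cross-check against a direct multcomp call on the same model
  d <- data.frame(y = v, g = stats::relevel(factor(g), "DMSO"))
  ref <- summary(multcomp::glht(stats::aov(y ~ g, d),
                                linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(sort(t$comparisons$p_adj), sort(as.numeric(ref$test$pvalues)),
               tolerance = 5e-3)
})

test_that("two-way ANOVA F values match hand-computed sums of squares", {
  # 2x2 with 2 replicates per cell: SSA=72, SSB=32, SSI=8, MSE=0.5
  v <- c(1, 2, 3, 4, 5, 6, 11, 12)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(c("b1", "b2", "b1", "b2"), each = 2)
  t <- two_way_anova_bonferroni(v, A, B,
                                comparisons = list(
                                  list(c("a2", "b2"), c("a1", "b2")),
                                  list(c("a2", "b1"), c("a1", "b1"))))
  tab <- attr(t, "anova_table")
  expect_equal(tab$F, c(144, 64, 16), tolerance = 1e-12)
  # contrast (a2,b2) vs (a1,b2): diff 8, se sqrt(0.5 * (1/2 + 1/2)) -> t = 8/sqrt(0.5)
  expect_equal(t$comparisons$statistic[1], 8 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(t$comparisons$p_adj,
               pmin(1, 2 * t$comparisons$p_raw), tolerance = 1e-12)

  # constant response: all-null path
  t0 <- two_way_anova_bonferroni(rep(3, 8), A, B)
  expect_equal(t0$global_stat, 0)
  expect_equal(t0$global_p, 1)
  expect_identical(nrow(t0$comparisons), 0L)

  # empty cell is named in the error
  expect_error(
    two_way_anova_bonferroni(c(1, 2, 3, 4, 5, 6),
                             c("a1", "a1", "a1", "a1", "a2", "a2"),
                             c("b1", "b1", "b2", "b2", "b1", "b1")),
    class = "staz_unbalanced_design_error", regexp = "a2.*b2")
})

test_that("test_result_table flattens results with stars", {
  t <- kruskal_dunn(c(1, 2, 3, 10, 11, 12),
                    rep(c("DMSO", "T"), each = 3), "DMSO")
  tab <- test_result_table(t)
  expect_identical(tab$comparison[1], "(global)")
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("method", "statistic", "raw_p", "adj_p", "stars")
                  %in% names(tab)))
})
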