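# Per-subject explant volumes as printed in the study's imaging table
VOL_NS <- c(5793, 6289, 6961)
VOL_BMP <- c(7514, 7586, 7763)
VOL_DIPY <- c(5936, 6325, 7137)

test_that("Shapiro-Wilk wrapper reproduces the reference W and flags degenerate samples", {
  res <- shapiro_wilk(VOL_BMP)
  expect_equal(res$statistic, 0.9440434862, tolerance = 1e-6)
  expect_equal(res$p, 0.5438972070, tolerance = 1e-6)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  flat <- shapiro_wilk(rep(3, 5))
  expect_true(is.na(flat$p))
  expect_match(flat$method, "degenerate")
})

test_that("one-way ANOVA matches a first-principles oracle and the printed volume p", {
  vols <- c(VOL_NS, VOL_BMP, VOL_DIPY)
  grp <- rep(c("NS", "BMP", "DIPY"), each = 3)
  res <- one_way_anova(vols, grp)
  ora <- oracle_anova(vols, grp)
  expect_equal(res$statistic, unname(ora["F"]), tolerance = 1e-10)
  expect_equal(res$p, unname(ora["p"]), tolerance = 1e-10)
  expect_equal(round(res$p, 3), 0.036)
  # unbalanced: dropping one missing value changes df, not validity
  res_u <- one_way_anova(c(vols, NA), c(grp, "NS"))
  expect_equal(res_u$df, c(2, 6))
})

test_that("ANOVA handles degenerate inputs by convention", {
  same <- one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  sep <- one_way_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_identical(sep$statistic, Inf)
  expect_equal(sep$p, 0)
})

test_that("ANOVA with two groups equals the squared pooled t", {
  set.seed(101)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5, 1)
    f <- one_way_anova(c(a, b), rep(c("a", "b"), c(4, 5)))
    t <- pooled_t_test(a, b)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p, t$p, tolerance = 1e-10)
  }
})

test_that("Tukey HSD agrees with a direct studentized-range computation", {
  set.seed(55)
  vals <- rnorm(15, rep(c(0, 1, 3), each = 5))
  grp <- rep(c("a", "b", "c"), each = 5)
  tk <- tukey_hsd(vals, grp)
  for (pr in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    row <- tk[tk$pair == paste(pr[1], pr[2], sep = "-"), ]
    expect_equal(row$p_adj, oracle_tukey_p(vals, grp, pr[1], pr[2]),
                 tolerance = 1e-6)
  }
  # identical groups compare with p = 1; well-separated ones with p ~ 0
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(tk0$p_adj, 1)
  vals2 <- c(rnorm(5), rnorm(5), rnorm(5, 10))
  tk2 <- tukey_hsd(vals2, grp)
  expect_true(all(tk2$p_adj[grepl("c", tk2$pair)] < 0.001))
})

test_that("pairwise volume t tests reproduce the printed 0.02 and 0.03", {
  expect_equal(round(pooled_t_test(VOL_BMP, VOL_NS)$p, 2), 0.02)
  expect_equal(round(pooled_t_test(VOL_BMP, VOL_DIPY)$p, 2), 0.03)
  ident <- pooled_t_test(c(2, 2), c(2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  bc <- bonferroni(pooled_t_test(VOL_BMP, VOL_NS), 2)
  expect_true(bc$adjusted)
  expect_equal(bc$p, 2 * pooled_t_test(VOL_BMP, VOL_NS)$p)
  expect_equal(bonferroni(pooled_t_test(VOL_BMP, VOL_NS), 1000)$p, 1)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- mann_whitney(a, b)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, oracle_mw_exact_p(a, b))
  set.seed(2)
  x <- rnorm(4); y <- rnorm(5, 0.5)
  expect_equal(mann_whitney(x, y)$p, oracle_mw_exact_p(x, y),
               tolerance = 1e-12)
  expect_equal(mann_whitney(rep(4, 3), rep(4, 4))$p, 1)
})

test_that("Mann-Whitney p-values are calibrated under the null", {
  set.seed(77)
  ps <- vapply(1:1000, function(i)
    mann_whitney(rnorm(8), rnorm(8))$p, 0)
  expect_lt(mean(ps <= 0.05), 0.065)
  expect_gt(mean(ps), 0.4)
})

test_that("Kruskal-Wallis and Dunn post hoc behave on separation and ties", {
  set.seed(314)
  vals <- c(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  grp <- rep(c("a", "b", "c"), each = 5)
  expect_lt(kruskal_wallis(vals, grp)$p, 0.01)
  expect_equal(kruskal_wallis(rep(7, 9), rep(c("a", "b", "c"), 3))$p, 1)
  dn <- dunn_posthoc(vals, grp)
  expect_true(all(dn$p_adj[grepl("c", dn$pair)] < 0.05))
  expect_gt(dn$p_adj[dn$pair == "a-b"], 0.5)
  expect_true(all(dn$p_adj >= dn$p))
  # symmetric under group relabeling
  dn2 <- dunn_posthoc(vals, rep(c("c", "b", "a"), each = 5))
  expect_equal(sort(abs(dn$z)), sort(abs(dn2$z)), tolerance = 1e-12)
})

test_that("small-sample ANOVA p is close to the full permutation p", {
  x <- c(1.371, -0.565, 0.363, 1.633, 1.404, 0.894, 3.512, 1.905, 4.018)
  g <- rep(1:3, each = 3)
  p_f <- one_way_anova(x, g)$p
  f0 <- oracle_anova(x, g)["F"]
  combos_a <- combn(9, 3, simplify = FALSE)
  hits <- 0; tot <- 0
  for (a in combos_a) {
    rest <- setdiff(1:9, a)
    for (b in combn(rest, 3, simplify = FALSE)) {
      gg <- integer(9); gg[a] <- 1; gg[b] <- 2; gg[setdiff(rest, b)] <- 3
      tot <- tot + 1
      if (oracle_anova(x, gg)["F"] >= f0 - 1e-12) hits <- hits + 1
    }
  }
  expect_lt(abs(p_f - hits / tot), 0.05)
})
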