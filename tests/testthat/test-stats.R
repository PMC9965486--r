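test_that("Mann-Whitney U reproduces exact small-sample p-values", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)    # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")
  # identical multisets: maximal p
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "at least two")
})

test_that("exact Mann-Whitney p matches full enumeration for all 4+4 splits", {
  vals <- c(1.3, 2.1, 3.7, 4.2, 5.9, 6.4, 7.8, 8.5)
  splits <- utils::combn(8, 4)
  for (j in seq_len(ncol(splits))) {
    x <- vals[splits[, j]]; y <- vals[-splits[, j]]
    expect_equal(mann_whitney_u(x, y)$p_value, enum_mwu_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon signed-rank handles sign-only and degenerate inputs", {
  expect_equal(wilcoxon_signed_rank(c(1.1, 2.2, 3.3, 4.4, 5.5))$p_value,
               2 / 2^5)
  expect_equal(wilcoxon_signed_rank(c(1.2, 2.3, 3.1, 4.4, 5.5, 6.1))$p_value,
               2 / 2^6)
  anti <- wilcoxon_signed_rank(c(-3.2, 3.2, -1.1, 1.1, -2.6, 2.6))
  expect_gte(anti$p_value, 0.99)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  # zero differences are dropped before testing
  r <- wilcoxon_signed_rank(c(0, 1.1, 2.2, 3.3, 4.4, 5.5))
  expect_equal(r$n_per_group, 5)
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-9)
  set.seed(67)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(tab)$p_value, enum_fisher_p(tab),
                 tolerance = 1e-9)
    # row exchange leaves the two-sided p unchanged
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("the printed FAF table gives 0.011 one-sided, 0.020 two-sided", {
  tab <- matrix(c(9, 29, 0, 22), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(tab, "greater")$p_value, 3), 0.011)
  expect_equal(round(fisher_exact_2x2(tab)$p_value, 3), 0.020)
})

test_that("ROC AUC and Youden cutoff follow the rank formulation", {
  r <- roc_with_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1), "greater-equal")
  expect_equal(r$auc, 1.0)
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$youden, 1.0)
  # perfectly separated in the decreasing direction
  r2 <- roc_with_cutoff(c(4, 3, 2, 1), c(1, 1, 0, 0), "less-than")
  expect_equal(r2$auc, 0)
  # ties get half credit
  r3 <- roc_with_cutoff(c(1, 1, 1, 1), c(0, 0, 1, 1), "greater-equal")
  expect_equal(r3$auc, 0.5)
  # null case: labels independent of scores
  set.seed(71)
  r4 <- roc_with_cutoff(rnorm(2000), rbinom(2000, 1, 0.5), "greater-equal")
  expect_lt(abs(r4$auc - 0.5), 0.05)
  expect_error(roc_with_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC of negated scores is the complement (no ties)", {
  set.seed(73)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  a1 <- roc_with_cutoff(s, l, "greater-equal")$auc
  a2 <- roc_with_cutoff(-s, l, "greater-equal")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  s <- c(rnorm(40, 1), rnorm(40, 0)); l <- rep(c(1, 0), each = 40)
  mine <- roc_with_cutoff(s, l, "greater-equal")
  ref <- pROC::roc(l, s, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  best <- pROC::coords(ref, "best", best.method = "youden", transpose = FALSE)
  expect_equal(mine$cutoff, best$threshold[nrow(best)], tolerance = 1e-9)
})

test_that("logistic fit recovers a null exposure and the 2x2 closed form", {
  set.seed(83)
  n <- 2000
  y <- rbinom(n, 1, 0.4)
  x <- rbinom(n, 1, 0.5)
  f <- logistic_adjusted(y, x)
  expect_true(f$ci95[1] < 1 && 1 < f$ci95[2])
  # single binary covariate: OR equals the cross-product ratio
  tab <- table(x, y)
  cp <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(f$odds_ratio, unname(cp), tolerance = 1e-6)
})

test_that("separation raises an explicit error, not a huge OR", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- y                                  # complete separation
  expect_error(logistic_adjusted(y, x), "separation")
  expect_error(logistic_adjusted(c(0, 1), c(0, 1)), "at least 10")
})

test_that("group differences at published effect sizes are detectable", {
  set.seed(89)
  reject <- replicate(200, {
    co <- make_metric_cohort()
    mann_whitney_u(co$ccfa_ratio[co$group == "amd_fellow"],
                   co$ccfa_ratio[co$group == "control"])$p_value < 0.05
  })
  expect_gt(mean(reject), 0.5)
})
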