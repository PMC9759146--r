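test_that("one-way ANOVA matches hand computation and degenerate contracts", {
  d <- data.frame(
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    g = rep(c("a", "b", "c"), each = 3)
  )
  res <- anova_oneway(d, "y", "g")
  expect_equal(res$F, 3) # SSB = 6 over df 2, SSW = 6 over df 6
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  same <- data.frame(y = rep(c(1, 1, 1), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(anova_oneway(same, "y", "g")$F, 0)
  expect_equal(anova_oneway(same, "y", "g")$p_raw, 1)
  apart <- data.frame(
    y = c(0, 0, 1, 10, 10, 11, 20, 20, 21),
    g = rep(c("a", "b", "c"), each = 3)
  )
  res2 <- anova_oneway(apart, "y", "g")
  expect_gt(res2$F, 100)
  expect_lt(res2$p_raw, 0.001)
  expect_error(anova_oneway(data.frame(y = 1:3, g = c("a", "a", "b")), "y", "g"), "at least two obs")
})

test_that("Bonferroni arithmetic and family sizes are exact", {
  expect_equal(bonferroni(0.001, 21), 0.021)
  expect_equal(bonferroni(0.1, 84), 1)
  expect_equal(bonferroni(0.0005, 84), 0.042)
  expect_equal(correction_count(3, 7), 21)
  expect_equal(correction_count(3, 7, 4), 84)
  expect_equal(correction_count(1, 1), 1)
})

test_that("distribution gates behave on null data and reject degenerate input", {
  set.seed(101)
  ks_ok <- sum(vapply(1:100, function(s) {
    normality_ks(rnorm(500))$p > 0.05
  }, logical(1)))
  expect_gte(ks_ok, 95)
  expect_error(normality_ks(rep(1, 10)), "Constant")
  d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), 20))
  lv <- homogeneity_levene(d, "y", "g")
  expect_true(lv$p > 0 && lv$p <= 1)
  # null Levene p-values are roughly uniform across seeds
  ps <- vapply(1:60, function(s) {
    dd <- data.frame(y = rnorm(45), g = rep(c("a", "b", "c"), 15))
    homogeneity_levene(dd, "y", "g")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("clinical correlations match closed forms", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(clinical_correlation(x, 2 * x)$r, 1)
  set.seed(5)
  y <- sample(x)
  # brute-force Spearman: Pearson correlation of the ranks
  rs <- clinical_correlation(x, y, method = "spearman")$r
  expect_equal(rs, cor(rank(x), rank(y)))
  expect_error(clinical_correlation(x, rep(1, 7)), "Constant")
  expect_error(clinical_correlation(x, y[1:3]), "paired")
})

test_that("logistic regression flags real effects and controls the null", {
  set.seed(33)
  null_p <- vapply(1:100, function(s) {
    logistic_fit(rnorm(40), rep(0:1, 20))$p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.9)
  x <- c(rnorm(25, 0), rnorm(25, 2))
  y <- rep(0:1, each = 25)
  fit <- logistic_fit(x, y)
  expect_gt(fit$coef, 0)
  expect_lt(fit$p, 0.01)
  expect_true(fit$ci95[1] < fit$coef && fit$coef < fit$ci95[2])
  td <- tidy(fit)
  expect_equal(td$estimate[2], fit$coef)
  expect_error(logistic_fit(rnorm(20), rep(1, 20)), "Both outcome classes")
  # complete separation falls back to a penalized fit with a warning
  xs <- c(rnorm(15, -5), rnorm(15, 5))
  expect_warning(sep <- logistic_fit(xs, rep(0:1, each = 15)), "separation")
  expect_true(sep$separated)
  expect_gt(sep$coef, 0)
})

test_that("ROC analysis follows the pair-counting identity and Youden rule", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  flat <- roc_analysis(rep(1, 10), rep(0:1, 5))
  expect_equal(flat$auc, 0.5)
  # orientation: reversed predictor gives the same AUC with direction "<"
  rev <- roc_analysis(-c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))
  expect_equal(rev$auc, 1)
  expect_equal(rev$direction, "<")
  expect_error(roc_analysis(1:4, rep(1, 4)), "Both outcome classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(40)
  y <- as.integer(x + rnorm(40) > 0)
  a0 <- roc_analysis(x, y)$auc
  expect_equal(roc_analysis(exp(x), y)$auc, a0)
  expect_equal(roc_analysis(x^3, y)$auc, a0)
  expect_equal(roc_analysis(atan(x), y)$auc, a0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  x <- rnorm(60)
  y <- as.integer(x + rnorm(60) > 0.2)
  ours <- roc_analysis(x, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE, direction = "<")))
  expect_equal(ours, max(ref, 1 - ref), tolerance = 1e-12)
})

test_that("band-wise comparison corrects p-values and orders pairwise tests", {
  set.seed(61)
  d <- tidyr::expand_grid(
    band = c("alpha", "beta"),
    group = rep(c("fsiq_lt80", "fsiq_gt80", "hc"), each = 10)
  )
  d$CA <- rnorm(nrow(d), mean = ifelse(d$band == "beta" & d$group == "fsiq_lt80", -2, 0), sd = 0.5)
  res <- compare_bands(d, "CA", m = 84, group_order = c("fsiq_lt80", "fsiq_gt80", "hc"))
  expect_equal(nrow(res), 2)
  beta <- res[res$band == "beta", ]
  expect_lt(beta$p_bonferroni, 0.05)
  expect_equal(beta$p_bonferroni, min(1, 84 * beta$p_raw))
  expect_lt(beta$p_AB, 0.05)
  expect_lt(beta$p_AC, 0.05)
  expect_gt(beta$p_BC, 0.05)
  alpha_row <- res[res$band == "alpha", ]
  expect_gt(alpha_row$p_bonferroni, 0.05)
})
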