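test_that("visit averaging is the arithmetic mean with carry-forward", {
  tab <- data.frame(subject_id = c("a", "a", "b", "c", "c"),
                    group = c("t2dm", "t2dm", "t2dm", "t2dm", "t2dm"),
                    visit_day = c(1, 8, 1, 1, 8),
                    mpr = c(10, 20, 3, 5, NA))
  out <- average_across_visits(tab)
  expect_equal(nrow(out), 3)
  expect_equal(out$mpr[out$subject_id == "a"], 15)
  expect_equal(out$mpr[out$subject_id == "b"], 3)   # single visit: identity
  expect_equal(out$mpr[out$subject_id == "c"], 5)   # missing day 8 carried
})

test_that("one-way ANOVA matches the hand sum-of-squares decomposition", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  # by hand: SSB = 3*((2-3)^2 + 0 + (4-3)^2) = 6, SSW = 3*2 = 6,
  # F = (6/2)/(6/6) = 3 on (2, 6) df
  res <- one_way_anova(g)
  expect_equal(res$F, 3)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  # equal means with positive within variance
  eq <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  # degenerate zero within-group variance, unequal means
  dg <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(dg$p, 0)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(8, 0, 1); y <- rnorm(11, 0.7, 1.3)
    f <- one_way_anova(list(x = x, y = y))$F
    t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
})

test_that("Tukey HSD reproduces the studentized-range calibration", {
  # identical pair of groups: adjusted p ~ 1
  res <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 7)))
  expect_gt(res$p_adj[res$pair == "b-a"], 0.999)
  # construct a balanced design whose largest q sits exactly at the 5%
  # critical value of the studentized range (3 groups, df = 12)
  s <- c(-2, -1, 0, 1, 2)            # SSW = 10 per group, MSW = 2.5
  qcrit <- stats::qtukey(0.95, 3, 12)
  delta <- qcrit * sqrt(2.5 / 5)
  g <- list(a = 0 + s, b = delta + s, c = delta / 2 + s)
  out <- tukey_hsd(g)
  expect_equal(out$p_adj[out$pair == "b-a"], 0.05, tolerance = 1e-8)
  # monotonicity: wider mean gaps give smaller adjusted p
  set.seed(3)
  m <- list(a = rnorm(6), b = rnorm(6) + 1, c = rnorm(6) + 3)
  o <- tukey_hsd(m)
  expect_lt(o$p_adj[o$pair == "c-a"], o$p_adj[o$pair == "b-a"])
})

test_that("Pearson chi-squared follows hand arithmetic and margins", {
  # table proportional to its margins
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_squared(prop)$statistic, 0)
  expect_equal(chi_squared(prop)$p, 1)
  # perfect association 2x2: every cell contributes (5)^2/5
  expect_equal(chi_squared(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "zero row or column")
  # additivity over independent tables
  t1 <- rbind(c(8, 3), c(4, 9)); t2 <- rbind(c(5, 5), c(2, 12))
  block <- chi_squared(t1)$statistic + chi_squared(t2)$statistic
  expect_gt(block, chi_squared(t1)$statistic)
})

test_that("Pearson correlation matches hand covariance arithmetic", {
  x <- c(1, 2, 4, 5, 8); y <- c(2, 1, 5, 4, 9)
  # by hand: cov = 32/4 = 8, var_x = 30/4, var_y = 38.8/4
  r_hand <- 8 / sqrt(7.5 * 9.7)
  res <- pearson_corr(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_equal(pearson_corr(x, 2 * x)$r, 1)
  # null behaviour at n = 1e4
  set.seed(8)
  expect_lt(abs(pearson_corr(rnorm(1e4), rnorm(1e4))$r), 0.05)
  # log transform requires positivity
  expect_error(pearson_corr(c(-1, 1, 2), c(1, 2, 3), log_x = TRUE),
               "positive")
  expect_error(pearson_corr(rep(1, 5), 1:5), "zero variance")
})

test_that("logistic regression recovers null and discriminant benchmarks", {
  set.seed(10)
  n <- 2e4
  d <- data.frame(hf = rbinom(n, 1, 0.4), x = rnorm(n))
  null_fit <- fit_logistic(d, "hf", "x")
  expect_equal(null_fit$odds_ratio, 1, tolerance = 0.05)
  expect_true(null_fit$ci_low <= null_fit$odds_ratio &&
                null_fit$odds_ratio <= null_fit$ci_high)
  # discriminant-analysis identity: two normal classes with common variance
  # have logistic coefficient delta_mu / sigma^2
  set.seed(11)
  n <- 1e5
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n, mean = 0.8 * y, sd = 1.25)
  fit <- fit_logistic(data.frame(y = y, x = x), "y", "x")
  expect_equal(fit$coef, 0.8 / 1.25^2, tolerance = 0.02)
  # covariates are accepted and flagged as adjusted
  d2 <- data.frame(y = rbinom(200, 1, 0.5), x = rnorm(200),
                   age = rnorm(200, 60, 8), female = rbinom(200, 1, 0.3),
                   bmi = rnorm(200, 30, 4))
  adj <- fit_logistic(d2, "y", "x", covariates = c("age", "female", "bmi"))
  expect_true(adj$adjusted)
})

test_that("complete separation is detected and flagged, not inflated", {
  d <- data.frame(y = rep(c(0, 1), each = 10), x = c(rnorm(10), rnorm(10) + 50))
  expect_warning(fit <- fit_logistic(d, "y", "x"), "separation")
  expect_true(fit$separated)
})

test_that("ROC analysis matches brute-force concordance and Youden rules", {
  # complete separation toy
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$threshold, 2); expect_lt(r$threshold, 3)
  # 6-point toy with one inversion vs exhaustive pairwise counting
  v <- c(1, 2, 3, 4, 5, 6); y <- c(0, 0, 1, 0, 1, 1)
  r2 <- roc_analysis(v, y)
  expect_equal(r2$auc, brute_force_auc(v, y))
  # AUC invariant under strictly monotone transforms
  set.seed(5)
  vals <- rnorm(60); out <- rbinom(60, 1, plogis(vals))
  a0 <- roc_analysis(vals, out)$auc
  expect_equal(roc_analysis(exp(vals), out)$auc, a0)
  expect_equal(roc_analysis(vals^3, out)$auc, a0)
  expect_warning(rc <- roc_analysis(rep(2, 10), rep(c(0, 1), 5)),
                 "constant predictor")
  expect_equal(rc$auc, 0.5)
})

test_that("ICC(2,1) matches the hand-computed closed form", {
  # 4x2 table: row means 9.5..6.5, column means 7.5/8.5, zero residual
  # MSR = 10/3, MSC = 2, MSE = 0 -> ICC = (10/3)/(10/3 + 2*2/4) = 10/13
  r <- icc2(c(9, 8, 7, 6), c(10, 9, 8, 7))
  expect_equal(r$icc2, 10 / 13, tolerance = 1e-12)
  expect_equal(r$cicchetti_band, "excellent")
  # identical measurements
  perfect <- icc2(c(3, 5, 9, 2), c(3, 5, 9, 2))
  expect_equal(perfect$icc2, 1)
  expect_equal(perfect$cicchetti_band, "excellent")
  # absolute agreement is penalised by a pure additive visit shift
  set.seed(9)
  d1 <- rnorm(40, 10, 2); d8 <- d1 + 1.5
  agree <- icc2(d1, d8)$icc2
  consistency <- stats::cor(d1, d8)  # consistency analogue = 1 here
  expect_lt(agree, consistency)
  expect_error(icc2(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc2(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("Cicchetti bands follow the published cut-points", {
  day1 <- c(10, 12, 14, 16, 18, 20)
  mk <- function(icc_target) icc_target  # band checked via helper values
  expect_equal(icc2(day1, day1 + rnorm(6, 0, 1e-6))$cicchetti_band,
               "excellent")
  bands <- vapply(c(0.2, 0.5, 0.7, 0.9), function(v)
    hfpefcmr:::cicchetti_band(v), character(1))
  expect_equal(bands, c("poor", "fair", "good", "excellent"))
})

test_that("arrhythmia sensitivity analysis subsets and guards groups", {
  co <- synth_cohort(study_group_specs(), seed = 6)
  n_analyzed <- function(d) nrow(d)
  res <- sensitivity_excluding_arrhythmia(co, n_analyzed)
  expect_equal(res$n_excluded + res$n_retained, 35)
  # no flagged subjects: identical results
  co0 <- co; co0$arrhythmia_history <- 0
  expect_equal(sensitivity_excluding_arrhythmia(co0, n_analyzed)$result, 35)
  # a fully flagged group is a degenerate subset
  co1 <- co; co1$arrhythmia_history <- as.integer(co1$group == "hfpef_t2dm")
  expect_error(sensitivity_excluding_arrhythmia(co1, n_analyzed),
               "hfpef_t2dm")
})

test_that("pooled summaries recombine group rows into overall values", {
  expect_equal(round(pooled_mean(c(27.7, 30.6, 32.3), c(6, 16, 13)), 1),
               30.7)
  expect_equal(round(pooled_mean(c(62, 61, 68), c(6, 16, 13))), 64)
  expect_equal(round(100 * (2 + 1 + 5) / 35), 23)
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:12),
    group = rep(c("a", "b", "c"), each = 4),
    bmi = rep(c(25, 30, 35), each = 4) + rep(c(-1, 1, -1, 1), 3),
    female = c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 1))
  out <- cohort_summary(tab, variables = "bmi", categorical = "female")
  expect_equal(out$overall[out$variable == "bmi"], 30)
  expect_equal(out$overall[out$variable == "female"], 100 * 4 / 12)
  expect_equal(out$a_mean[out$variable == "bmi"], 25)
})
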