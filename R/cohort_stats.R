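#' Average measurements across visits
#'
#' For parameters measured at two or more visits, the subject-level value is
#' the mean of all available measurements; a missing visit simply drops out
#' of the mean.
#'
#' @param table A `cohort_table` data frame (one row per subject-visit).
#' @return A data frame with one row per subject; numeric variables averaged
#'   over visits, non-numeric columns taken from the first visit, plus a
#'   `n_visits` column.
#' @export
average_across_visits <- function(table) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  ids <- unique(table$subject_id)
  num_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                      "visit_day")
  other <- setdiff(names(table), c(num_cols, "visit_day"))
  rows <- lapply(ids, function(id) {
    sub <- table[table$subject_id == id, , drop = FALSE]
    rec <- sub[1, other, drop = FALSE]
    for (nm in num_cols) rec[[nm]] <- mean(sub[[nm]], na.rm = TRUE)
    rec$n_visits <- nrow(sub)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_group_list <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) return(values)
  split(values, groups)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: between/within mean-square F with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param values Either a list of per-group numeric vectors, or a numeric
#'   vector accompanied by `groups`.
#' @param groups Optional grouping factor when `values` is a vector.
#' @return A list with `F`, `p`, `df` and the per-group means.
#' @export
one_way_anova <- function(values, groups = NULL) {
  g <- as_group_list(values, groups)
  g <- lapply(g, function(x) x[!is.na(x)])
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(vapply(g, length, 1L) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), vapply(g, length, 1L)), levels = names(g))
  means <- vapply(g, mean, numeric(1))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0) {
    # degenerate: no within-group variance
    if (max(means) - min(means) == 0)
      return(list(F = 0, p = 1, df = c(length(g) - 1, length(y) - length(g)),
                  means = means))
    return(list(F = Inf, p = 0, df = c(length(g) - 1, length(y) - length(g)),
                means = means))
  }
  tab <- stats::anova(stats::lm(y ~ f))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df, means = means)
}

#' Tukey HSD post hoc comparisons
#'
#' Pairwise comparisons after a one-way ANOVA via the studentized range
#' distribution; unequal group sizes use the Tukey-Kramer standard error
#' `sqrt(MSW/2 * (1/n_i + 1/n_j))`.
#'
#' @inheritParams one_way_anova
#' @return A data frame with one row per group pair: `pair`, `diff`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups = NULL) {
  g <- as_group_list(values, groups)
  g <- lapply(g, function(x) x[!is.na(x)])
  if (length(g) < 2) stop("need at least 2 groups")
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), vapply(g, length, 1L)), levels = names(g))
  tk <- stats::TukeyHSD(stats::aov(y ~ f))$f
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Pearson chi-squared test on a contingency table
#'
#' @param counts Matrix of counts, categories x groups.
#' @return A list with `statistic`, `df`, `p` and the expected counts.
#' @export
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0))
    stop("all expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Pearson correlation with optional log transforms
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom. Skewed positive variables (such as
#' Pentraxin-3) can be natural-log transformed via the flags.
#'
#' @param x,y Numeric vectors.
#' @param log_x,log_y Apply `log()` before correlating (requires strictly
#'   positive values).
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y, log_x = FALSE, log_y = FALSE) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (log_x) { if (any(x <= 0)) stop("log_x requires positive x"); x <- log(x) }
  if (log_y) { if (any(y <= 0)) stop("log_y requires positive y"); y <- log(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Logistic regression for HFpEF discrimination
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' HFpEF indicator on one predictor, optionally adjusted for covariates
#' (age, sex, BMI in the adjusted models). The odds ratio is per unit of the
#' (possibly log-transformed) predictor, with a Wald 95% CI. Complete or
#' quasi-complete separation is detected and flagged rather than silently
#' reported as an inflated estimate.
#'
#' @param data Data frame.
#' @param outcome Name of the binary outcome column (0/1 or logical).
#' @param predictor Name of the predictor column.
#' @param covariates Optional character vector of covariate columns.
#' @param log_predictor Natural-log transform the predictor (for skewed
#'   biomarkers such as Pentraxin-3).
#' @return A list of class `logistic_result`: `predictor`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `coef`, `se`, `adjusted`, `covariates`,
#'   `separated`, `converged`, `n`.
#' @export
fit_logistic <- function(data, outcome, predictor, covariates = NULL,
                         log_predictor = FALSE) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("outcome must be binary with both classes present")
  x <- data[[predictor]]
  if (log_predictor) {
    if (any(x <= 0, na.rm = TRUE))
      stop("log transform requires a strictly positive predictor")
    x <- log(x)
  }
  d <- data.frame(.y = y, .x = x)
  rhs <- ".x"
  for (cv in covariates) {
    d[[cv]] <- data[[cv]]
    rhs <- paste(rhs, "+", cv)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  b <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  # quasi-complete separation drives |beta| and its SE jointly to infinity
  if (abs(b) > 10 || se > 10) separated <- TRUE
  if (separated)
    warning("possible complete or quasi-complete separation for predictor `",
            predictor, "`; the odds ratio is unreliable")
  structure(list(predictor = predictor, odds_ratio = exp(b),
                 ci_low = exp(b - stats::qnorm(0.975) * se),
                 ci_high = exp(b + stats::qnorm(0.975) * se),
                 p = sm[".x", "Pr(>|z|)"], coef = b, se = se,
                 adjusted = length(covariates) > 0,
                 covariates = covariates %||% character(),
                 separated = separated, converged = fit$converged,
                 n = nrow(d)),
            class = "logistic_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC analysis with Youden-index operating point
#'
#' Empirical ROC over all observed thresholds (via pROC), AUC by the
#' trapezoid/Mann-Whitney statistic with a DeLong 95% CI, and the
#' Youden-optimal threshold (maximising sensitivity + specificity - 1, ties
#' broken toward higher specificity) with its sensitivity, specificity,
#' predictive values and accuracy.
#'
#' @param values Numeric predictor.
#' @param outcome Binary outcome (0/1 or logical), 1 = case.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return A list of class `roc_result`: `auc`, `auc_ci`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `direction`.
#' @export
roc_analysis <- function(values, outcome, ci_method = c("delong", "bootstrap"),
                         boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  y <- if (is.logical(outcome)) as.integer(outcome) else outcome
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (stats::sd(values) == 0) {
    warning("constant predictor: AUC 0.5 with a degenerate threshold")
    return(structure(list(auc = 0.5, auc_ci = c(NA_real_, NA_real_),
                          threshold = values[1], sensitivity = NA_real_,
                          specificity = NA_real_, ppv = NA_real_,
                          npv = NA_real_, accuracy = NA_real_,
                          direction = NA_character_),
                     class = "roc_result"))
  }
  r <- pROC::roc(response = y, predictor = values, quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- withCallingHandlers(
    as.numeric(pROC::ci.auc(r, method = ci_method, boot.n = boot_n))[c(1, 3)],
    warning = function(w) {
      # pROC flags the degenerate AUC == 1 interval; the CI is still valid
      if (grepl("always 1-1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  co <- co[is.finite(co$threshold), , drop = FALSE]
  youden <- co$sensitivity + co$specificity - 1
  best <- which(youden == max(youden))
  if (length(best) > 1)
    best <- best[which.max(co$specificity[best])]
  thr <- co$threshold[best]
  sens <- co$sensitivity[best]; spec <- co$specificity[best]
  pred_pos <- if (r$direction == "<") values > thr else values < thr
  tp <- sum(pred_pos & y == 1); fp <- sum(pred_pos & y == 0)
  fn <- sum(!pred_pos & y == 1); tn <- sum(!pred_pos & y == 0)
  structure(list(auc = auc, auc_ci = ci, threshold = thr,
                 sensitivity = sens, specificity = spec,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 accuracy = (tp + tn) / length(y),
                 direction = r$direction),
            class = "roc_result")
}

#' Test-retest ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation from the two-way ANOVA mean squares:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` for `n`
#' subjects and `k` visits, with the standard F-based 95% confidence
#' interval and Cicchetti's interpretation bands (< 0.40 poor, 0.40-0.59
#' fair, 0.60-0.74 good, >= 0.75 excellent).
#'
#' @param day1,day8 Paired measurements (complete, n >= 3).
#' @param conf_level Confidence level for the interval.
#' @return A list of class `icc_result`: `icc2`, `ci`, `cicchetti_band`,
#'   `n`, `ms` (the mean squares).
#' @export
icc2 <- function(day1, day8, conf_level = 0.95) {
  keep <- stats::complete.cases(day1, day8)
  m <- cbind(day1[keep], day8[keep])
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(as.vector(m)) == 0)
    stop("ICC undefined: zero total variance")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse == 0 && msc == 0)  # exact agreement: degenerate interval
    return(structure(list(icc2 = 1, ci = c(1, 1),
                          cicchetti_band = "excellent", n = n,
                          ms = c(msr = msr, msc = msc, mse = mse)),
                     class = "icc_result"))
  alpha <- 1 - conf_level
  # McGraw & Wong F-based interval for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc2 = icc, ci = c(lo, hi),
                 cicchetti_band = cicchetti_band(icc), n = n,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

cicchetti_band <- function(icc) {
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Sensitivity analysis excluding arrhythmia history
#'
#' Reruns an analysis on the subset of subjects without a positive history
#' of atrial arrhythmia.
#'
#' @param table Cohort data frame with an `arrhythmia_history` column
#'   (0/1 or logical).
#' @param analysis_fn Function taking the (subset) cohort table and
#'   returning its results.
#' @return A list with `result` (the analysis output on the subset),
#'   `n_excluded` and `n_retained`.
#' @export
sensitivity_excluding_arrhythmia <- function(table, analysis_fn) {
  if (!"arrhythmia_history" %in% names(table))
    stop("`arrhythmia_history` flag missing from the cohort table")
  flag <- as.logical(table$arrhythmia_history)
  sub <- table[!flag, , drop = FALSE]
  lost <- setdiff(unique(table$group), unique(sub$group))
  if (length(lost) > 0)
    stop("exclusion removes every subject of group: ",
         paste(lost, collapse = ", "))
  list(result = analysis_fn(sub),
       n_excluded = sum(flag), n_retained = nrow(sub))
}

#' Size-weighted pooled mean
#'
#' Recombines per-group summary rows into the overall cohort value:
#' `sum(n_g * mean_g) / sum(n_g)`. For a binary variable, pass per-group
#' proportions to obtain the overall proportion.
#'
#' @param means Per-group means (or proportions).
#' @param n Per-group sizes.
#' @return The pooled mean.
#' @examples
#' pooled_mean(c(27.7, 30.6, 32.3), c(6, 16, 13))  # overall BMI
#' @export
pooled_mean <- function(means, n) {
  stopifnot(length(means) == length(n), all(n >= 0), sum(n) > 0)
  sum(means * n) / sum(n)
}

#' Patient-characteristics summary table
#'
#' Per-group mean +/- SD for continuous variables and n (%) for binary
#' variables, an overall (size-weighted) column, and a p-value per row:
#' one-way ANOVA for continuous rows, Pearson chi-squared for binary rows.
#'
#' @param table Subject-level cohort data frame (one row per subject; see
#'   [average_across_visits()]).
#' @param variables Character vector of continuous variable columns.
#' @param categorical Character vector of binary (0/1) variable columns.
#' @param group_col Name of the group column.
#' @return A data frame with one row per variable: per-group `mean` and
#'   `sd` (or count and percent), `overall`, and `p`.
#' @export
cohort_summary <- function(table, variables, categorical = character(),
                           group_col = "group") {
  g <- factor(table[[group_col]])
  ns <- table(g)
  rows <- list()
  for (nm in variables) {
    x <- table[[nm]]
    means <- tapply(x, g, mean, na.rm = TRUE)
    sds <- tapply(x, g, stats::sd, na.rm = TRUE)
    p <- tryCatch(one_way_anova(x, g)$p, error = function(e) NA_real_)
    rec <- data.frame(variable = nm, type = "continuous",
                      overall = pooled_mean(means, as.numeric(ns)),
                      p = p)
    for (lv in levels(g)) {
      rec[[paste0(lv, "_mean")]] <- means[[lv]]
      rec[[paste0(lv, "_sd")]] <- sds[[lv]]
    }
    rows[[nm]] <- rec
  }
  for (nm in categorical) {
    x <- as.integer(as.logical(table[[nm]]))
    cnt <- tapply(x, g, sum)
    tab <- rbind(yes = cnt, no = as.numeric(ns) - cnt)
    p <- tryCatch(chi_squared(tab)$p, error = function(e) NA_real_)
    rec <- data.frame(variable = nm, type = "categorical",
                      overall = 100 * sum(cnt) / sum(ns), p = p)
    for (lv in levels(g)) {
      rec[[paste0(lv, "_mean")]] <- cnt[[lv]]
      rec[[paste0(lv, "_sd")]] <- 100 * cnt[[lv]] / ns[[lv]]
    }
    rows[[nm]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
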