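#' Kruskal-Wallis omnibus test with Dunn pairwise comparisons
#'
#' Omnibus rank-based H test (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn z tests for all group pairs, Bonferroni-adjusted with
#' the usual cap at 1.
#'
#' @param groups Named list mapping group label to numeric values.
#' @return List: `H`, `p_value` (omnibus), `pairwise` (`data.frame` with
#'   `group1`, `group2`, `z`, `p_adjusted`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  npairs <- ncol(pairs)
  pw <- apply(pairs, 2, function(p) {
    z <- (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[p[1]] + 1 / n[p[2]]))
    c(z = unname(z), p = min(1, 2 * stats::pnorm(-abs(z)) * npairs))
  })
  list(H = unname(kw$statistic), p_value = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = pw["z", ], p_adjusted = pw["p", ],
                             row.names = NULL))
}

#' Empirical ROC curve with Youden-index cutpoint
#'
#' Classification rule: `score > threshold` predicts the positive class.
#' Candidate thresholds are midpoints between consecutive distinct scores,
#' plus sentinels below and above the observed range. AUC is the trapezoid
#' area, which equals the tie-corrected Mann-Whitney concordance. The
#' Youden cutpoint maximizes `sensitivity + specificity - 1`; ties are
#' broken toward higher specificity.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical or 0/1 labels; `TRUE`/1 is the positive class.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutpoint`, `youden_J`.
#' @export
roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] <= t), numeric(1))
  # trapezoid over the ROC polygon (fpr descending as thr ascends)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-9)   # tolerance so exact ties survive
  best <- best[which.max(spec[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutpoint = thr[best],
                 youden_J = J[best]),
            class = "roc_result")
}

#' Youden-index-optimal threshold of a ROC curve
#'
#' @param roc_obj A `roc_result`.
#' @return The threshold maximizing J, ties broken toward higher
#'   specificity.
#' @export
youden_cutpoint <- function(roc_obj) {
  stopifnot(inherits(roc_obj, "roc_result"))
  roc_obj$youden_cutpoint
}

#' Classify by cutpoint and test association with clinical status
#'
#' Predicts positive when `score > cutpoint`, builds the confusion matrix
#' with exact binomial (Clopper-Pearson) 95% CIs for sensitivity,
#' specificity and accuracy, and tests the 2x2 table by two-sided Fisher
#' exact test.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 truth (positive = 1).
#' @param cutpoint Classification threshold.
#' @return List: `confusion` (tp/fp/tn/fn), `sensitivity`, `specificity`,
#'   `accuracy` (each a list with `estimate`, `ci`), `fisher_p`.
#' @export
classify_and_test <- function(scores, labels, cutpoint) {
  labels <- as.logical(labels)
  pred <- scores > cutpoint
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  est <- function(x, n) {
    ci <- if (n > 0) as.numeric(stats::binom.test(x, n)$conf.int)
    else c(NA_real_, NA_real_)
    list(estimate = if (n > 0) x / n else NA_real_, ci = ci)
  }
  tab <- matrix(c(tp, fn, fp, tn), 2, 2)
  list(confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = est(tp, tp + fn),
       specificity = est(tn, tn + fp),
       accuracy = est(tp + tn, tp + fp + tn + fn),
       fisher_p = stats::fisher.test(tab)$p.value)
}

# Ridge-penalized logistic regression by Newton iterations; the penalty
# lambda/2 * ||beta||^2 excludes the intercept. Small and explicit so LOOCV
# folds can be checked against direct penalized-likelihood optimization.
ridge_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, as.matrix(X))
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

predict_ridge <- function(beta, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% beta))
}

#' Leave-one-out cross-validated penalized logistic classification
#'
#' For each held-out sample a ridge-penalized logistic regression is fitted
#' on the remainder (penalty chosen by inner 5-fold cross-validation on
#' each training fold) and the sample is predicted positive at probability
#' 0.5. Accuracy carries an exact binomial (Clopper-Pearson) 95% CI. The
#' ridge penalty keeps training folds with degenerate labels or separable
#' data well-posed.
#'
#' @param features Numeric matrix or data.frame of predictors.
#' @param labels Logical or 0/1 outcomes.
#' @param lambda_grid Candidate penalties for the inner CV (default
#'   `10^seq(-2, 1, by = 1)`); a single value skips the inner CV.
#' @param seed Seed controlling inner-CV fold assignment.
#' @return List: `accuracy`, `ci`, `predictions` (`data.frame` with
#'   `index`, `prob`, `predicted`, `label`, `lambda`).
#' @export
loocv_logistic <- function(features, labels, lambda_grid = 10^(-2:1),
                           seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(as.logical(labels))
  n <- nrow(X)
  if (n < 4L) stop("need n >= 4", call. = FALSE)

  inner_lambda <- function(Xtr, ytr, fold_seed) {
    if (length(lambda_grid) == 1L) return(lambda_grid)
    m <- nrow(Xtr)
    folds <- with_seed(fold_seed, sample(rep_len(1:5, m)))
    loss <- vapply(lambda_grid, function(l) {
      dev <- 0
      for (f in 1:5) {
        tr <- folds != f
        if (all(ytr[tr] == ytr[tr][1])) {
          p <- mean(ytr[tr])
          p <- min(max(p, 1e-6), 1 - 1e-6)
          dev <- dev - sum(ytr[!tr] * log(p) + (1 - ytr[!tr]) * log(1 - p))
        } else {
          b <- ridge_logistic(Xtr[tr, , drop = FALSE], ytr[tr], l)
          p <- pmin(pmax(predict_ridge(b, Xtr[!tr, , drop = FALSE]),
                         1e-9), 1 - 1e-9)
          dev <- dev - sum(ytr[!tr] * log(p) + (1 - ytr[!tr]) * log(1 - p))
        }
      }
      dev
    }, numeric(1))
    lambda_grid[which.min(loss)]
  }

  preds <- lapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    l <- inner_lambda(Xtr, ytr, stage_seed(seed, paste0("fold:", i)))
    b <- ridge_logistic(Xtr, ytr, l)
    prob <- predict_ridge(b, X[i, , drop = FALSE])
    data.frame(index = i, prob = prob, predicted = prob > 0.5,
               label = y[i] == 1, lambda = l)
  })
  preds <- do.call(rbind, preds)
  correct <- sum(preds$predicted == preds$label)
  bt <- stats::binom.test(correct, n)
  list(accuracy = correct / n, ci = as.numeric(bt$conf.int),
       predictions = preds)
}

#' Multivariate logistic regression of clinical status
#'
#' Maximum-likelihood logistic fit of the outcome on tumor fraction plus
#' covariates, with per-coefficient Wald z tests. Perfect separation and
#' rank deficiency are reported as diagnostic flags, not errors.
#'
#' @param labels Logical or 0/1 outcome.
#' @param tf Numeric tumor fractions.
#' @param covariates `data.frame` of additional covariates (e.g. age, sex,
#'   institution); factors are expanded by the usual treatment contrasts.
#' @return List: `coefficients` (`data.frame` with `term`, `estimate`,
#'   `std_error`, `z`, `p_value`), `separation`, `rank_deficient`,
#'   `deviance`, `null_deviance`.
#' @export
multivariate_logistic <- function(labels, tf, covariates = NULL) {
  df <- data.frame(y = as.numeric(as.logical(labels)), tf = tf)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (nrow(df) <= ncol(df)) stop("need n > number of coefficients",
                                 call. = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  aliased <- is.na(stats::coef(fit))
  list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 std_error = co[, 2], z = co[, 3],
                                 p_value = co[, 4], row.names = NULL),
       separation = sep, rank_deficient = any(aliased),
       deviance = fit$deviance, null_deviance = fit$null.deviance)
}

#' Per-group sample size for a one-way ANOVA at given power
#'
#' Smallest integer `n` per group such that the fixed-effects one-way ANOVA
#' F test with `k` groups, effect size Cohen's f, and significance level
#' alpha reaches the target power, using the noncentral F distribution with
#' noncentrality `f^2 * k * n`, `df1 = k - 1`, `df2 = k * (n - 1)`.
#'
#' @param cohens_f Cohen's f effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param k_groups Number of groups (>= 2).
#' @return Integer n per group.
#' @export
anova_sample_size <- function(cohens_f, alpha = 0.05, power = 0.80,
                              k_groups = 3) {
  stopifnot(cohens_f > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            k_groups >= 2)
  for (n in 2:10000) {
    df1 <- k_groups - 1
    df2 <- k_groups * (n - 1)
    lambda <- cohens_f^2 * k_groups * n
    crit <- stats::qf(1 - alpha, df1, df2)
    if (1 - stats::pf(crit, df1, df2, ncp = lambda) >= power) return(n)
  }
  stop("power not reachable within n = 10000", call. = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Normal approximation with tie-corrected variance (no continuity
#' correction), as used for two-group comparisons of skewed measures.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List: `U` (rank-sum statistic for `a`), `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty",
                                     call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier estimation with the censoring indicator inverted (events
#' become censorings and vice versa), so the "survival" curve describes
#' follow-up duration; the median and IQR are read off that curve.
#'
#' @param times Follow-up times (>= 0).
#' @param event_flags 0/1 or logical; 1 = the study event occurred (these
#'   observations are censored in the reversed analysis).
#' @return List: `median`, `iqr` (named length-2 vector, 25% and 75%
#'   quantiles of follow-up), `fit` (the `survfit` object).
#' @export
reverse_km_median_followup <- function(times, event_flags) {
  stopifnot(all(times >= 0))
  ev <- as.numeric(as.logical(event_flags))
  fit <- survival::survfit(survival::Surv(times, 1 - ev) ~ 1)
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))
  qq <- q$quantile
  list(median = unname(qq[2]),
       iqr = c(`25%` = unname(qq[1]), `75%` = unname(qq[3])),
       fit = fit)
}
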