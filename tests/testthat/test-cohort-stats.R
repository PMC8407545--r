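test_that("Kruskal-Wallis/Dunn caps adjusted p at 1 and matches small-sample formulas", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kd <- kruskal_dunn(same)
  expect_true(all(kd$pairwise$p_adjusted == 1))

  # two-group omnibus equals the tie-corrected normal-approximation rank test
  set.seed(10)
  a <- rnorm(15); b <- rnorm(12, 0.8)
  kd2 <- kruskal_dunn(list(a = a, b = b))
  expect_equal(kd2$p_value, wilcoxon_rank_sum(a, b)$p_value,
               tolerance = 1e-9)

  # hand-computed H on a small untied instance
  g <- list(a = c(1, 5, 8, 11), b = c(2, 6, 9, 12), c = c(3, 7, 10, 13))
  N <- 12; r <- rank(unlist(g))
  Ri <- tapply(r, rep(names(g), each = 4), sum)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / 4) - 3 * (N + 1)
  expect_equal(kruskal_dunn(g)$H, H, tolerance = 1e-9)
  expect_error(kruskal_dunn(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("ROC handles perfect, null and enumerable cases", {
  r <- roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_J, 1)
  expect_gt(r$youden_cutpoint, 2)
  expect_lte(r$youden_cutpoint, 3)

  set.seed(11)
  scores <- rnorm(2000)
  labels <- sample(rep(c(0, 1), 1000))
  expect_lt(abs(roc(scores, labels)$auc - 0.5), 0.03)
  expect_error(roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals the tie-corrected rank statistic", {
  set.seed(12)
  for (rep in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- c(sample(1:8, n1, TRUE), sample(1:8, n0, TRUE)) +
      (if (rep %% 2) 0 else rnorm(n1 + n0, 0, 0.01))
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    a <- roc(scores, labels)$auc
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
    expect_equal(a, mean(cmp), tolerance = 1e-12)
  }
})

test_that("Youden cutpoint equals exhaustive search with the specificity tie rule", {
  set.seed(13)
  for (rep in 1:50) {
    scores <- round(rnorm(20), 1)
    labels <- runif(20) < plogis(2 * scores)
    if (!any(labels) || all(labels)) next
    r <- roc(scores, labels)
    cut <- youden_cutpoint(r)
    # brute force over a fine threshold sweep
    sweep <- sort(unique(c(scores - 0.05, scores + 0.05)))
    J <- vapply(sweep, function(t)
      mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1, numeric(1))
    expect_equal(r$youden_J, max(J), tolerance = 1e-9)
    # achieved J at the reported cutpoint equals the maximum
    Jcut <- mean(scores[labels] > cut) + mean(scores[!labels] <= cut) - 1
    expect_equal(Jcut, max(J), tolerance = 1e-9)
    # tie rule: no threshold with equal J has higher specificity
    spec_cut <- mean(scores[!labels] <= cut)
    ties <- sweep[abs(J - max(J)) < 1e-9]
    spec_ties <- vapply(ties, function(t) mean(scores[!labels] <= t),
                        numeric(1))
    expect_gte(spec_cut + 1e-12, max(spec_ties))
  }
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  skip_if(!any(labels) || all(labels))
  ours <- roc(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("cutpoint classification reproduces printed arithmetic and Fisher enumeration", {
  # 21 of 23 PN below the cutpoint -> specificity 91%
  scores <- c(rep(0.01, 21), rep(0.9, 2), rep(0.9, 9), rep(0.01, 3))
  labels <- rep(c(FALSE, TRUE), c(23, 12))
  cls <- classify_and_test(scores, labels, 0.041)
  expect_equal(cls$confusion$tn, 21)
  expect_equal(cls$confusion$fp, 2)
  expect_equal(round(100 * cls$specificity$estimate), 91)
  expect_true(cls$specificity$ci[1] <= cls$specificity$estimate &
                cls$specificity$estimate <= cls$specificity$ci[2])

  # perfectly separated 10 vs 10: Fisher p = 2 / choose(20, 10)
  s <- c(rep(0, 10), rep(1, 10)); l <- rep(c(FALSE, TRUE), each = 10)
  p <- classify_and_test(s, l, 0.5)$fisher_p
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)

  # degenerate: everything predicted negative
  cls0 <- classify_and_test(rep(0, 10), rep(c(TRUE, FALSE), 5), 1)
  expect_equal(cls0$sensitivity$estimate, 0)
  expect_lte(cls0$sensitivity$ci[1], 0)
})

test_that("LOOCV ridge logistic: separable, null and fold-by-fold oracle", {
  # perfectly separable single feature
  x <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 10)
  res <- loocv_logistic(x, y, lambda_grid = 0.01)
  expect_equal(res$accuracy, 1)

  # permuted labels -> chance accuracy
  set.seed(15)
  xn <- matrix(rnorm(200), ncol = 1)
  yn <- sample(rep(c(TRUE, FALSE), 100))
  resn <- loocv_logistic(xn, yn, lambda_grid = 1)
  expect_lt(abs(resn$accuracy - 0.5), 0.12)

  # n = 6 instance: each fold equals direct penalized-likelihood optimization
  X6 <- matrix(c(0.2, -1.4, 0.7, 1.9, -0.3, 1.1), ncol = 1)
  y6 <- c(0, 0, 0, 1, 0, 1)
  lam <- 0.5
  res6 <- loocv_logistic(X6, y6, lambda_grid = lam)
  for (i in 1:6) {
    nll <- function(b) {
      eta <- b[1] + X6[-i, 1] * b[2]
      -sum(y6[-i] * eta - log1p(exp(eta))) + lam / 2 * b[2]^2
    }
    b <- optim(c(0, 0), nll, method = "BFGS")$par
    p_or <- plogis(b[1] + X6[i, 1] * b[2])
    expect_equal(res6$predictions$prob[i], p_or, tolerance = 1e-4)
  }
})

test_that("multivariate logistic regression finds tf and holds covariate type-I error", {
  set.seed(16)
  hits <- 0; cov_hits <- 0; reps <- 60
  for (r in 1:reps) {
    n <- 300
    tf <- runif(n, 0, 0.3)
    age <- rnorm(n, 40, 10)
    y <- runif(n) < plogis(-2 + 15 * tf)
    fit <- multivariate_logistic(y, tf, data.frame(age = age))
    co <- fit$coefficients
    hits <- hits + (co$p_value[co$term == "tf"] < 0.05)
    cov_hits <- cov_hits + (co$p_value[co$term == "age"] < 0.05)
  }
  expect_gte(hits / reps, 0.9)
  expect_lte(cov_hits / reps, 0.15)

  # null model deviance; duplicated covariate flagged as rank-deficient
  y <- rep(c(TRUE, FALSE), 20)
  tf0 <- rep(0.1, 40)
  fit0 <- multivariate_logistic(y, tf0, data.frame(z = rnorm(40)))
  expect_equal(fit0$deviance, fit0$null_deviance, tolerance = 0.5)
  x <- rnorm(40)
  fit_dup <- multivariate_logistic(y, x, data.frame(dup = x))
  expect_true(fit_dup$rank_deficient)
})

test_that("ANOVA sample size matches the noncentral-F and Monte-Carlo oracles", {
  expect_equal(anova_sample_size(0.6, 0.05, 0.80, 3), 10)

  # monotone in effect size
  f_grid <- c(0.2, 0.3, 0.4, 0.6, 0.8)
  ns <- vapply(f_grid, anova_sample_size, numeric(1))
  expect_true(all(diff(ns) <= 0))

  # Monte-Carlo power oracle at f = 0.25 (simulated one-way ANOVAs):
  # group means (-1, 0, 1) * f * sqrt(3/2) at sigma = 1 give Cohen's f
  f <- 0.25; k <- 3
  n_exact <- anova_sample_size(f, 0.05, 0.80, k)
  exact_power <- function(n)
    1 - pf(qf(0.95, k - 1, k * (n - 1)), k - 1, k * (n - 1),
           ncp = f^2 * k * n)
  mc_power <- function(n, reps = 20000) {
    means <- c(-1, 0, 1) * f * sqrt(3 / 2)
    x <- matrix(rnorm(reps * k * n, rep(means, each = n)), nrow = k * n)
    g <- rep(1:k, each = n)
    gm <- rowsum(x, g) / n
    ssb <- colSums((gm - rep(colMeans(x), each = k))^2 * n)
    ssw <- colSums((x - gm[g, ])^2)
    F <- (ssb / (k - 1)) / (ssw / (k * n - k))
    mean(F > qf(0.95, k - 1, k * n - k))
  }
  set.seed(17)
  for (n in c(n_exact - 1L, n_exact)) {
    p_mc <- mc_power(n)
    se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(p_mc - exact_power(n)), 4 * se)
  }
  expect_gte(exact_power(n_exact), 0.80)
  expect_lt(exact_power(n_exact - 1L), 0.80)
})

test_that("Wilcoxon rank-sum statistic equals exhaustive rank computation", {
  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  far <- wilcoxon_rank_sum(1:10, 101:110)
  expect_lt(far$p_value, 0.001)

  a <- c(3.1, 0.2, 5.5, 2.2, 4.0); b <- c(1.1, 6.3, 0.9, 2.8, 3.5)
  res <- wilcoxon_rank_sum(a, b)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(res$U), U)
})

test_that("reverse Kaplan-Meier recovers follow-up medians", {
  # no study events: reversed curve drops at every time
  res <- reverse_km_median_followup(c(100, 200, 300, 400, 500),
                                    rep(0, 5))
  expect_equal(res$median, 300)

  expect_equal(reverse_km_median_followup(250, 0)$median, 250)

  # 8-observation mixed instance vs hand product-limit on reversed events
  times <- c(100, 150, 200, 250, 300, 350, 400, 450)
  ev <- c(0, 1, 0, 0, 1, 0, 0, 0)  # study events at 150 and 300
  res8 <- reverse_km_median_followup(times, ev)
  # reversed: events (follow-up endings) at all times with ev = 0
  at_risk <- 8:1
  surv <- cumprod(ifelse(ev == 0, (at_risk - 1) / at_risk, 1))
  med_hand <- times[which(surv <= 0.5)[1]]
  expect_equal(res8$median, med_hand)
  expect_true(res8$iqr[1] <= res8$median & res8$median <= res8$iqr[2])
})
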