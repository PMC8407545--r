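mk_timeline <- function(tf_days, tf, detected = rep(TRUE, length(tf)),
                        sld_days = NULL, sld = NULL,
                        recist = NULL, therapy = integer(0)) {
  sld_df <- if (!is.null(sld_days))
    data.frame(day = sld_days, sld = sld,
               recist = recist %||% rep("SD", length(sld_days)))
  serial_timeline("p1", data.frame(day = tf_days, tf = tf,
                                   detected = detected),
                  sld_df, therapy)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("plasma-SLD matching follows the nearest/30-day/no-interceding-therapy rules", {
  # nearest of two eligible SLDs
  tl <- mk_timeline(100, 0.1, sld_days = c(90, 140), sld = c(3, 4))
  m <- match_sld_tf(tl)
  expect_equal(m$sld_day, 90)
  expect_equal(m$gap_days, 10)

  # beyond 30 days -> dropped; exactly 30 retained
  expect_equal(nrow(match_sld_tf(mk_timeline(100, 0.1, sld_days = 135,
                                             sld = 3))), 0L)
  expect_equal(nrow(match_sld_tf(mk_timeline(100, 0.1, sld_days = 130,
                                             sld = 3))), 1L)

  # interceding therapy change excludes the pair
  tl3 <- mk_timeline(100, 0.1, sld_days = 80, sld = 3, therapy = 90L)
  expect_equal(nrow(match_sld_tf(tl3)), 0L)

  # gap ties break toward the earlier SLD
  tl4 <- mk_timeline(100, 0.1, sld_days = c(90, 110), sld = c(3, 4))
  expect_equal(match_sld_tf(tl4)$sld_day, 90)
})

test_that("matching is invariant under day translation", {
  base <- mk_timeline(c(50, 130), c(0.1, 0.2), sld_days = c(60, 120),
                      sld = c(3, 5), therapy = 90L)
  shifted <- mk_timeline(c(50, 130) + 500, c(0.1, 0.2),
                         sld_days = c(60, 120) + 500, sld = c(3, 5),
                         therapy = 590L)
  m0 <- match_sld_tf(base); m1 <- match_sld_tf(shifted)
  expect_equal(m1$sld_day - 500, m0$sld_day)
  expect_equal(m1$tf, m0$tf)
  expect_equal(m1$gap_days, m0$gap_days)
})

test_that("correlation of matched pairs matches direct formulas and planted truth", {
  line <- data.frame(sld = 1:6, tf = 0.05 * (1:6))
  expect_equal(correlate(line)$r, 1)

  five <- data.frame(sld = c(2.2, 4.8, 3.1, 6.0, 5.5),
                     tf = c(0.02, 0.09, 0.05, 0.11, 0.08))
  r_hand <- sum(scale(five$sld) * scale(five$tf)) / 4
  expect_equal(correlate(five)$r, r_hand, tolerance = 1e-12)

  set.seed(18)
  rs <- replicate(100, {
    tf <- runif(200, 0, 0.4)
    z <- scale(tf)[, 1]
    sld <- 0.4 * z + sqrt(1 - 0.16) * rnorm(200)  # planted r = 0.4
    correlate(data.frame(sld = sld, tf = tf))$r
  })
  expect_lt(abs(mean(rs) - 0.4), 0.05)
  expect_error(correlate(line[1:2, ]), ">= 3")
  expect_error(correlate(data.frame(sld = c(1, 1, 1), tf = 1:3 / 10)),
               "zero variance")
})

test_that("serial normalization anchors the lowest detected value at zero", {
  s <- data.frame(tf = c(0.02, 0.08), detected = c(TRUE, TRUE))
  expect_equal(normalize_serial(s), c(0, 2))

  s2 <- data.frame(tf = rep(0.05, 4), detected = TRUE)
  expect_equal(normalize_serial(s2), rep(0, 4))

  s3 <- data.frame(tf = c(0.001, 0.05, 0.10),
                   detected = c(FALSE, TRUE, TRUE))
  expect_equal(normalize_serial(s3), c(-1, 0, 1))

  # invariance to positive rescaling of the whole series
  s4 <- data.frame(tf = c(0.03, 0.06, 0.12), detected = TRUE)
  expect_equal(normalize_serial(s4),
               normalize_serial(transform(s4, tf = tf * 7.3)))
  expect_error(normalize_serial(data.frame(tf = 0.1, detected = FALSE)),
               "no detected")
})

test_that("fold change divides later by earlier detected tumor fraction", {
  expect_equal(fold_change(0.02, 0.28), 14)
  expect_equal(fold_change(0.05, 0.05), 1)
  expect_error(fold_change(0.02, 0.28, detected_a = FALSE), "undetected")
})

test_that("lead time measures molecular re-detection ahead of radiographic progression", {
  tl <- mk_timeline(c(0, 60, 164), c(0.2, 0.001, 0.021),
                    detected = c(TRUE, FALSE, TRUE),
                    sld_days = c(0, 70, 253), sld = c(5, 0, 2),
                    recist = c("NONE", "CR", "PD"))
  expect_equal(lead_time(tl), 89)
  expect_equal(lead_time(tl, progression = "sld_rebound"), 89)

  same_day <- mk_timeline(c(0, 60, 100), c(0.2, 0.001, 0.05),
                          detected = c(TRUE, FALSE, TRUE),
                          sld_days = c(0, 100), sld = c(5, 8),
                          recist = c("NONE", "PD"))
  expect_equal(lead_time(same_day), 0)

  no_prog <- mk_timeline(c(0, 60, 100), c(0.2, 0.001, 0.05),
                         detected = c(TRUE, FALSE, TRUE),
                         sld_days = c(0, 100), sld = c(5, 5),
                         recist = c("NONE", "SD"))
  expect_null(lead_time(no_prog))

  never_redetected <- mk_timeline(c(0, 60), c(0.2, 0.001),
                                  detected = c(TRUE, FALSE),
                                  sld_days = 100, sld = 8, recist = "PD")
  expect_null(lead_time(never_redetected))
})

test_that("synthetic serial trajectories couple tumor fraction and SLD directionally", {
  cfg <- default_sim_config(seed = 77L, fragments_per_sample = 1)
  coh <- simulate_cohort(cfg, level = "counts")
  truth <- coh$truth[coh$truth$cohort == "MPNST", ]
  agree <- 0; total <- 0
  for (pid in unique(truth$participant_id)) {
    tt <- truth[truth$participant_id == pid, ]
    ss <- coh$sld[coh$sld$participant_id == pid, ]
    if (nrow(tt) < 2) next
    dtf <- diff(tt$true_tf)
    dsld <- diff(ss$sld)
    ok <- sign(dtf) == sign(dsld) | (abs(dtf) < 0.01)
    agree <- agree + sum(ok); total <- total + length(ok)
  }
  expect_gte(agree / total, 0.8)
})
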