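test_that("cohort CNA profiles follow the event catalogue rules", {
  cfg <- default_sim_config()
  g <- build_toy_genome(cfg, 1L)

  expect_equal(nrow(sample_cna_profile("HEALTHY", g, 1L, cfg)), 0L)

  # every MPNST draw carries the NF1-locus loss (and SUZ12)
  for (s in 1:20) {
    ev <- sample_cna_profile("MPNST", g, s, cfg)
    expect_true("NF1 loss" %in% ev$label)
    expect_true("SUZ12 loss" %in% ev$label)
    expect_true(all(ev$copy_number != 2L))
  }

  # PN: always NF1, never SMARCA2 at its default probability of 0
  pn_labels <- unlist(lapply(1:50, function(s)
    sample_cna_profile("PN", g, s, cfg)$label))
  expect_true(all(table(pn_labels)["NF1 loss"] == 50))
  expect_false("SMARCA2 loss" %in% pn_labels)

  expect_error(sample_cna_profile("TUMOUR", g, 1L, cfg), "unknown cohort")
})

test_that("fragment mixture reproduces the closed-form count ratio", {
  # tf = 0.4 with one whole-chromosome copy-3 gain, flat bias:
  # expected count ratio gained/neutral = (0.6*2 + 0.4*3)/2 = 1.2
  g <- flat_grid(c(cG = 100, cN = 100))
  ev <- data.frame(chrom = "cG", start = 0, end = 100e6, copy_number = 3L)
  cfg <- default_sim_config()
  n <- 1e6
  fr <- simulate_fragments(g, ev, 0.4, n, cfg$length_model, seed = 11L)
  cts <- bin_counts(fr, g)$counts
  n_g <- sum(cts[g$bins$chrom == "cG"]); n_n <- sum(cts[g$bins$chrom == "cN"])
  ratio <- n_g / n_n
  # delta-method standard error of the ratio n_g / (n - n_g)
  p <- 1.2 / 2.2
  se <- sqrt(p * (1 - p) / n) / (1 - p)^2
  expect_lt(abs(ratio - 1.2), 3 * se)
  expect_equal(n_g + n_n, n)  # count conservation incl. midpoint assignment
})

test_that("tf = 0 fragments follow the healthy length component", {
  g <- flat_grid(c(c1 = 100))
  cfg <- default_sim_config()
  fr <- simulate_fragments(g, NULL, 0, 5e4, cfg$length_model, seed = 2L)
  healthy_ref <- plasmafrac:::with_seed(3L, plasmafrac:::draw_lengths(
    5e4, cfg$length_model, "healthy"))
  tumor_ref <- plasmafrac:::with_seed(4L, plasmafrac:::draw_lengths(
    5e4, cfg$length_model, "tumor"))
  d_h <- ks_two_sample(fr$length, healthy_ref)$D
  d_t <- ks_two_sample(fr$length, tumor_ref)$D
  expect_lt(d_h, d_t)
})

test_that("size selection enriches tumor origin per the Bayes-rule oracle", {
  g <- flat_grid(c(c1 = 100))
  cfg <- default_sim_config()
  tf <- 0.4
  fr <- simulate_fragments(g, NULL, tf, 2e5, cfg$length_model, seed = 21L)
  kept <- size_select(fr, 90, 150)
  observed <- mean(kept$tumor_origin)
  # oracle: posterior tumor probability of a retained fragment by numerical
  # integration of the two truncated length densities over 90..150
  bp <- 90:150
  p_t <- sum(plasmafrac:::length_model_density(bp, cfg$length_model, "tumor"))
  p_h <- sum(plasmafrac:::length_model_density(bp, cfg$length_model, "healthy"))
  oracle <- tf * p_t / (tf * p_t + (1 - tf) * p_h)
  expect_gt(observed, tf)
  se <- sqrt(oracle * (1 - oracle) / nrow(kept))
  expect_lt(abs(observed - oracle), 4 * se)
})

test_that("negative-binomial bin counts have the specified means and Poisson limit", {
  g <- flat_grid(c(c1 = 100))
  # tf = 0, flat bias: every bin mean equals mean_depth
  cts <- simulate_bin_counts(g, NULL, 0, 300, Inf, seed = 5L)
  expect_lt(abs(mean(cts) - 300), 3 * sqrt(300 / n_bins(g)))

  # tf -> 1, c = 4 bin has mean 2 x mean_depth (tf capped just below 1)
  ev <- data.frame(chrom = "c1", start = 0, end = 100e6, copy_number = 4L)
  cts4 <- simulate_bin_counts(g, ev, 1 - 1e-9, 300, Inf, seed = 6L)
  expect_lt(abs(mean(cts4) - 600), 4 * sqrt(600 / n_bins(g)))

  # dispersion -> Inf limit: variance approaches the Poisson variance
  g1 <- flat_grid(c(c1 = 1000), bin_mb = 0.01)  # 1e5 bins for variance est.
  mu <- 100
  v_pois <- var(simulate_bin_counts(g1, NULL, 0, mu, Inf, seed = 7L))
  v_nb <- var(simulate_bin_counts(g1, NULL, 0, mu, 20, seed = 8L))
  expect_lt(abs(v_pois - mu) / mu, 0.05)
  expect_gt(v_nb, mu * (1 + mu / 20) * 0.9)  # clearly overdispersed
})

test_that("simulate_cohort meets the study's design structure deterministically", {
  cfg <- tiny_config(seed = 42L)
  coh <- simulate_cohort(cfg, level = "counts")
  m <- coh$meta
  expect_equal(sum(m$cohort == "HEALTHY"), cfg$n_healthy)
  expect_equal(sum(m$cohort == "PN"), cfg$n_pn)
  # healthy/PN are single-sample
  expect_true(all(table(m$participant_id[m$cohort != "MPNST"]) == 1))
  # MPNST serial counts never exceed 6
  expect_true(all(table(m$participant_id[m$cohort == "MPNST"]) <= 6))
  # first sample of each participant is pretreatment
  first <- do.call(rbind, lapply(split(m, m$participant_id),
                                 function(d) d[which.min(d$day), ]))
  expect_true(all(first$treatment_state == "PRETREATMENT"))
  # washout labels honor the 21-day rule against the therapy table
  expect_silent(validate_washout(m, coh$therapy))
  # SLD days strictly increasing per participant
  expect_silent(read_sld_check <- {
    for (pid in unique(coh$sld$participant_id))
      stopifnot(all(diff(coh$sld$day[coh$sld$participant_id == pid]) > 0))
  })

  coh2 <- simulate_cohort(cfg, level = "counts")
  expect_identical(coh, coh2)
})

test_that("at study scale, MPNST serial sampling averages 3 per participant", {
  cfg <- default_sim_config(seed = 9L)
  coh <- simulate_cohort(default_sim_config(
    seed = 9L, fragments_per_sample = 1), level = "counts")
  k <- table(coh$meta$participant_id[coh$meta$cohort == "MPNST"])
  expect_equal(length(k), 14L)
  expect_lt(abs(mean(k) - 3), 0.8)
  expect_lte(max(k), 6)
})

test_that("noise-free SLD coupling gives perfect correlation with true tf", {
  cfg <- tiny_config(seed = 3L, sld_noise_sd = 0, sld_slope = 1,
                     sld_intercept = 0, sld_day_jitter = 0)
  coh <- simulate_cohort(cfg, level = "counts")
  truth <- coh$truth[coh$truth$cohort == "MPNST", ]
  merged <- merge(truth, coh$sld, by = c("participant_id", "day"))
  merged <- merged[!duplicated(merged[c("participant_id", "day")]), ]
  expect_gt(nrow(merged), 3)
  expect_equal(cor(merged$sld, merged$true_tf), 1, tolerance = 1e-9)
})
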