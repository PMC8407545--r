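test_that("fragments are binned by midpoint with count conservation", {
  g <- flat_grid(c(c1 = 10))
  # midpoint 1,000,035 -> bin 2
  fr <- frag_df("c1", 999950, 1000120)
  expect_equal(which(bin_counts(fr, g)$counts > 0), 2L)

  set.seed(1)
  fr2 <- frag_df("c1", starts <- sample(0:(9.9e6), 500), starts + 160)
  bc <- bin_counts(fr2, g)
  expect_equal(sum(bc$counts), 500L)
  perm <- fr2[sample(nrow(fr2)), ]
  expect_equal(bin_counts(perm, g)$counts, bc$counts)

  expect_error(bin_counts(frag_df("cZ", 0, 160), g), "unknown chromosome")
})

test_that("bias correction is the identity on flat data and removes planted GC bias", {
  g <- flat_grid(c(c1 = 300, c2 = 300))
  lr <- correct_bias(rep(200L, n_bins(g)), g)
  expect_true(all(abs(lr$log2_ratio) < 1e-9))
  expect_equal(median(lr$log2_ratio, na.rm = TRUE), 0, tolerance = 1e-9)

  # planted exponential GC bias (counts proportional to 2^(a*gc)), no CNAs,
  # >= 500 bins; residual error comes only from the LOESS fit
  cfg <- default_sim_config()
  gt <- build_toy_genome(cfg, seed = 13L)
  counts <- round(2000 * 2^(1.5 * (gt$bins$gc - 0.45)) * gt$bins$mappability)
  lr2 <- correct_bias(counts, gt)
  v <- lr2$log2_ratio[!lr2$mask]
  expect_gt(length(v), 500)
  expect_gte(mean(abs(v) < 0.1), 0.95)
})

test_that("low-mappability and zero-count bins are masked", {
  chroms <- data.frame(name = "c1", length = 100e6)
  map <- rep(1, 100); map[7] <- 0.5
  g <- genome_grid(chroms, 1e6, gc = rep(0.45, 100), mappability = map)
  counts <- rep(200L, 100); counts[20] <- 0L
  lr <- correct_bias(counts, g)
  expect_true(is.na(lr$log2_ratio[7]))
  expect_true(is.na(lr$log2_ratio[20]))
  expect_error(correct_bias(rep(0L, 100), g), "zero")
})

test_that("panel normalization removes recurrent artifacts and keeps real CNAs", {
  g <- flat_grid(c(c1 = 300, c2 = 300))
  nb <- n_bins(g)
  base <- rep(3000, nb)
  artifact <- rep(1, nb); artifact[50] <- 2^0.5  # recurrent +0.5 bin
  mk <- function(extra, seed) correct_bias(
    plasmafrac:::with_seed(seed, rpois(nb, base * artifact * extra)), g)
  panel <- lapply(1:6, function(s) mk(1, s))

  # sample equal to the panel expectation -> ~0 everywhere incl. artifact bin
  s0 <- panel_normalize(mk(1, 99), panel)
  expect_lt(max(abs(s0$log2_ratio), na.rm = TRUE), 0.15)
  expect_lt(abs(s0$log2_ratio[50]), 0.15)

  # planted CNA absent from the panel is preserved
  cna <- rep(1, nb); cna[201:300] <- 2^0.585
  s1 <- panel_normalize(mk(cna, 100), panel)
  expect_equal(mean(s1$log2_ratio[201:300], na.rm = TRUE), 0.585,
               tolerance = 0.05)

  # identical panel members and sample -> exact zeros
  flat <- correct_bias(rep(3000L, nb), g)
  s2 <- panel_normalize(flat, list(flat, flat, flat))
  expect_true(all(abs(s2$log2_ratio) < 1e-9, na.rm = TRUE))
  expect_error(panel_normalize(flat, list(flat, flat)), ">= 3")
})

test_that("threshold calls use strict inequalities at 0.58 and -1.0", {
  lr <- c(0.59, 0.58, -1.01, -1.0, 0, NA)
  expect_equal(threshold_call(lr),
               c("GAIN", "NEUTRAL", "LOSS", "NEUTRAL", "NEUTRAL", "MASKED"))
  expect_true(all(threshold_call(rep(0, 10)) == "NEUTRAL"))
})

test_that("cohort aggregation averages profiles and tracks event frequencies", {
  g <- flat_grid(c(c1 = 10))
  mk <- function(x) structure(list(log2_ratio = x, mask = is.na(x)),
                              class = "corrected_lr")
  one <- mk(c(0.3, rep(0, 9)))
  agg1 <- aggregate_cohort(list(one), g)
  expect_equal(agg1$mean_log2_ratio, one$log2_ratio)

  two <- aggregate_cohort(list(mk(c(0.3, rep(0, 9))),
                               mk(c(-0.3, rep(0, 9)))), g)
  expect_equal(two$mean_log2_ratio[1], 0)

  ev <- aggregate_cohort(list(mk(c(0.7, rep(0, 9))), mk(c(-1.2, rep(0, 9)))), g)
  expect_equal(ev$gain_freq[1], 0.5)
  expect_equal(ev$loss_freq[1], 0.5)
  expect_error(aggregate_cohort(list(), g), "empty")
})

test_that("planted events at tf = 1 land on the threshold anchors end-to-end", {
  g <- recovery_grid()
  ev <- recovery_events()
  counts <- simulate_bin_counts(g, ev, 1 - 1e-12, 2000, Inf, seed = 15L)
  lr <- correct_bias(counts, g)
  gain_bins <- g$bins$chrom == "chrA" & g$bins$start < 120e6
  loss_bins <- g$bins$chrom == "chrB" & g$bins$start < 110e6
  expect_equal(mean(lr$log2_ratio[gain_bins], na.rm = TRUE),
               log2(3 / 2), tolerance = 0.05)
  expect_equal(mean(lr$log2_ratio[loss_bins], na.rm = TRUE),
               -1, tolerance = 0.05)
})

test_that("MPNST cohorts show NF1-locus loss that healthy cohorts lack", {
  cfg <- default_sim_config()
  g <- build_toy_genome(cfg, seed = 44L)
  nf1 <- cna_catalogue()
  nf1 <- nf1[nf1$label == "NF1 loss", ]
  nf1_bins <- g$bins$chrom == nf1$chrom &
    (g$bins$start + g$bins$end) / 2 >= nf1$start &
    (g$bins$start + g$bins$end) / 2 < nf1$end

  prof <- function(cohort, s) {
    ev <- sample_cna_profile(cohort, g, s, cfg)
    counts <- simulate_bin_counts(g, ev, 0.95, 800, Inf,
                                  seed = s + 1000L)
    correct_bias(counts, g)
  }
  mpnst <- lapply(1:6, function(s) prof("MPNST", s))
  healthy <- lapply(1:6, function(s) prof("HEALTHY", s))
  agg_m <- aggregate_cohort(mpnst, g, loss = -0.3)
  agg_h <- aggregate_cohort(healthy, g, loss = -0.3)
  expect_gt(max(agg_m$loss_freq[nf1_bins]), max(agg_h$loss_freq[nf1_bins]))
  expect_equal(max(agg_h$loss_freq[nf1_bins]), 0)
})
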