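# Small fixtures shared across tests; everything is built in code.

# Flat two-chromosome grid: constant GC and mappability so bias correction
# is an identity up to centering.
flat_grid <- function(chrom_mb = c(chrA = 300, chrB = 300), bin_mb = 1,
                      gc = 0.45, map = 1) {
  chroms <- data.frame(name = names(chrom_mb), length = chrom_mb * 1e6,
                       stringsAsFactors = FALSE)
  nb <- sum(ceiling(chrom_mb / bin_mb))
  genome_grid(chroms, bin_mb * 1e6, gc = rep(gc, nb), mappability = rep(map, nb))
}

# Fragment table helper.
frag_df <- function(chrom, start, end, sample_id = "S1") {
  data.frame(chrom = chrom, start = start, end = end, length = end - start,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# A 1.0-Gb-scale profile with one copy-3 arm and one copy-1 arm (>= 100
# bins each) used for tumor-fraction recovery tests.
recovery_events <- function() {
  data.frame(chrom = c("chrA", "chrB"), start = c(0, 0),
             end = c(120e6, 110e6), copy_number = c(3L, 1L),
             label = c("gain", "loss"), stringsAsFactors = FALSE)
}

recovery_grid <- function() {
  flat_grid(c(chrA = 240, chrB = 240, chrC = 240, chrD = 240))
}

# Directly simulated corrected log2-ratio profile: expected_log_ratio plus
# iid Gaussian noise. Bypasses counts when only the HMM is under test.
lr_profile <- function(grid, events, tf, noise_sd, seed) {
  cn <- plasmafrac:::bin_copy_number(grid, events)
  mu <- expected_log_ratio(cn, tf)
  lr <- plasmafrac:::with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  lr[grid$bins$mask] <- NA
  lr
}

# Tiny cohort config for pipeline-composition tests (fast, not the study
# conditions; study-scale checks use default_sim_config()).
tiny_config <- function(seed = 1L, ...) {
  default_sim_config(fragments_per_sample = 1.5e5,
                     n_healthy = 6L, n_pn = 6L, n_mpnst = 4L,
                     seed = seed, ...)
}
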