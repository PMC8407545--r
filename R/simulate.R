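#' Default simulation configuration
#'
#' Encodes the study conditions the cohort generator emulates: 16 healthy /
#' 23 PN / 14 MPNST participants, serial MPNST plasma samples (average 3,
#' maximum 6 per participant), MPNST-specific arm-level and focal copy-number
#' events, PN restricted to the focal NF1-locus loss, tumor-derived fragments
#' stochastically shorter than background cfDNA, and SLD imaging coupled to
#' true tumor fraction. The toy genome is 1.0 Gb over 8 autosomes plus a
#' masked chrX so sex-chromosome exclusion is exercised.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A named list (class `sim_config`).
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    # toy genome (Mb lengths); chrX present but always masked downstream
    chrom_lengths = c(chr1 = 180, chr2 = 160, chr3 = 150, chr4 = 140,
                      chr5 = 120, chr6 = 100, chr7 = 90, chr8 = 60,
                      chrX = 50) * 1e6,
    bin_width = 1e6,
    low_map_fraction = 0.03,
    # cohort sizes
    n_healthy = 16L, n_pn = 23L, n_mpnst = 14L,
    # tumor fraction: MPNST baseline uniform; healthy/PN shed no tumor DNA
    mpnst_tf_range = c(0.04, 0.40),
    pn_tf = 0, healthy_tf = 0,
    # fragment-level simulation
    fragments_per_sample = 4e5,
    length_model = list(
      healthy = list(mode = 167, sd = 25, di_mode = 320, di_sd = 40,
                     di_weight = 0.15),
      tumor = list(mode = 145, sd = 25),
      min_bp = 60, max_bp = 450),
    # count-level shortcut
    mean_depth = 200, dispersion = 100,
    # technical structure
    gc_bias_strength = 1,      # log2 units per unit GC deviation from 0.45
    sample_bias_sd = 0.05,     # sd (log2) of per-sample smooth coverage wave
    sample_bias_scale = 10,    # correlation length of the wave, in bins
    # CNA catalogue probabilities
    pn_cdkn2b_suz12_prob = 0.08,
    pn_smarca2_prob = 0,
    mpnst_arm_prob = 0.5,
    mpnst_focal_prob = 0.5,
    # serial sampling: at the study size (14 MPNST) a fixed multiset of
    # draw counts totalling 46 plasma samples (mean 3.3, max 6) is permuted
    # across participants; other cohort sizes fall back to these weights
    serial_count_multiset = c(1, 1, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 6, 6),
    serial_count_probs = c(0.14, 0.22, 0.28, 0.18, 0.10, 0.08),
    serial_interval_days = 75,
    trajectory_probs = c(response = 0.4, relapse = 0.4, progression = 0.2),
    # imaging coupling: sld (cm) = intercept + slope * true_tf + noise
    sld_intercept = 3, sld_slope = 25, sld_noise_sd = 1,
    sld_day_jitter = 15,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Build the toy genome grid
#'
#' Tiles the configured chromosomes into fixed-width bins, draws per-bin GC
#' from a smooth spatial process confined to `[0.3, 0.6]`, and sets
#' mappability near 1 with a configured fraction of low-mappability bins.
#'
#' @param config A [default_sim_config()] list.
#' @param seed Integer seed.
#' @return A `genome_grid`.
#' @export
build_toy_genome <- function(config = default_sim_config(), seed = config$seed) {
  chroms <- data.frame(name = names(config$chrom_lengths),
                       length = as.numeric(config$chrom_lengths),
                       stringsAsFactors = FALSE)
  grid0 <- genome_grid(chroms, config$bin_width)
  nb <- n_bins(grid0)
  with_seed(seed, {
    gc <- unlist(lapply(split(seq_len(nb), grid0$bins$chrom)[
      unique(grid0$bins$chrom)], function(i) {
        w <- cumsum(stats::rnorm(length(i)))
        if (length(i) > 1L) w <- (w - mean(w)) / max(stats::sd(w), 1e-9)
        0.45 + 0.075 * tanh(w) + stats::rnorm(length(i), 0, 0.005)
      }), use.names = FALSE)
    gc <- pmin(0.6, pmax(0.3, gc))
    map <- pmin(1, 1 - abs(stats::rnorm(nb, 0, 0.01)))
    low <- stats::runif(nb) < config$low_map_fraction
    map[low] <- stats::runif(sum(low), 0.4, 0.85)
    genome_grid(chroms, config$bin_width, gc = gc, mappability = map)
  })
}

# Catalogue of MPNST/NF1-associated events mapped onto toy coordinates.
# Toy chr4 stands in for chromosome 9 (p losses incl. CDKN2A/B, MTAP,
# SMARCA2; q gain), chr5 for chromosome 17 (q gain; NF1 and SUZ12 near the
# start of the q arm), chr6 for 6 (p loss), chr1/chr7/chr8 for 1q/7p/8q
# gains. Positions are fixed toy coordinates, not hg19 liftovers.
#' CNA event catalogue on the toy genome
#' @return `data.frame` of candidate events (`chrom`, `start`, `end`,
#'   `copy_number`, `label`, `class`).
#' @export
cna_catalogue <- function() {
  ev <- function(chrom, start, end, cn, label, class)
    data.frame(chrom = chrom, start = start, end = end, copy_number = cn,
               label = label, class = class, stringsAsFactors = FALSE)
  rbind(
    ev("chr1", 90e6, 180e6, 3L, "1q gain", "arm"),
    ev("chr7", 0, 45e6, 3L, "7p gain", "arm"),
    ev("chr8", 30e6, 60e6, 3L, "8q gain", "arm"),
    ev("chr4", 70e6, 140e6, 3L, "9q gain", "arm"),
    ev("chr5", 60e6, 120e6, 3L, "17q gain", "arm"),
    ev("chr6", 0, 50e6, 1L, "6p loss", "arm"),
    ev("chr4", 0, 70e6, 1L, "9p loss", "arm"),
    ev("chr4", 20e6, 23e6, 1L, "CDKN2A/B loss", "focal"),
    ev("chr4", 24e6, 27e6, 1L, "MTAP loss", "focal"),
    ev("chr4", 2e6, 5e6, 1L, "SMARCA2 loss", "focal"),
    ev("chr5", 66e6, 69e6, 1L, "SUZ12 loss", "focal"),
    ev("chr5", 62e6, 65e6, 1L, "NF1 loss", "focal"))
}

#' Draw a cohort-appropriate CNA profile
#'
#' HEALTHY draws are empty. PN always carries the focal NF1-locus loss, plus
#' CDKN2B/SUZ12 losses with a small configurable probability (SMARCA2 stays
#' copy-neutral at the default probability of 0). MPNST carries NF1 and
#' SUZ12 losses plus a random subset of the arm-level and focal catalogue.
#' Focal events are listed after arm events so they override overlapping
#' arm copy numbers.
#'
#' @param cohort One of `"HEALTHY"`, `"PN"`, `"MPNST"`.
#' @param grid A `genome_grid` (bounds check only).
#' @param seed Integer seed.
#' @param config Simulation config (event probabilities).
#' @return `data.frame` of events (possibly 0 rows).
#' @export
sample_cna_profile <- function(cohort, grid, seed,
                               config = default_sim_config()) {
  if (!cohort %in% cohort_levels)
    stop("unknown cohort: ", cohort, call. = FALSE)
  cat_ <- cna_catalogue()
  none <- cat_[0, ]
  with_seed(seed, {
    if (cohort == "HEALTHY") return(none)
    if (cohort == "PN") {
      keep <- cat_$label == "NF1 loss"
      keep <- keep | (cat_$label %in% c("CDKN2A/B loss", "SUZ12 loss") &
                        stats::runif(nrow(cat_)) < config$pn_cdkn2b_suz12_prob)
      keep <- keep | (cat_$label == "SMARCA2 loss" &
                        stats::runif(nrow(cat_)) < config$pn_smarca2_prob)
      return(cat_[keep & cat_$class == "focal", ])
    }
    # MPNST: NF1 + SUZ12 always; other events by class-specific probability
    u <- stats::runif(nrow(cat_))
    keep <- cat_$label %in% c("NF1 loss", "SUZ12 loss") |
      (cat_$class == "arm" & u < config$mpnst_arm_prob) |
      (cat_$class == "focal" & u < config$mpnst_focal_prob)
    out <- cat_[keep, ]
    out[order(match(out$class, c("arm", "focal"))), ]
  })
}

# Truncated-normal sampler via inverse CDF.
rtnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# Draw fragment lengths from one component of the length model.
draw_lengths <- function(n, model, origin = c("healthy", "tumor")) {
  origin <- match.arg(origin)
  lo <- model$min_bp; hi <- model$max_bp
  if (origin == "tumor")
    return(round(rtnorm(n, model$tumor$mode, model$tumor$sd, lo, hi)))
  h <- model$healthy
  di <- stats::runif(n) < h$di_weight
  len <- numeric(n)
  len[!di] <- rtnorm(sum(!di), h$mode, h$sd, lo, hi)
  len[di] <- rtnorm(sum(di), h$di_mode, h$di_sd, lo, hi)
  round(len)
}

# Density of the length model component on integer bp values (normalized on
# [min_bp, max_bp]); used by tests as a Bayes-rule oracle.
length_model_density <- function(bp, model, origin = c("healthy", "tumor")) {
  origin <- match.arg(origin)
  lo <- model$min_bp; hi <- model$max_bp
  dens <- function(m, s) {
    z <- stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s)
    ifelse(bp >= lo & bp <= hi, stats::dnorm(bp, m, s) / z, 0)
  }
  if (origin == "tumor") return(dens(model$tumor$mode, model$tumor$sd))
  h <- model$healthy
  (1 - h$di_weight) * dens(h$mode, h$sd) + h$di_weight * dens(h$di_mode, h$di_sd)
}

# Smooth per-sample log2 coverage wave: moving-average-filtered Gaussian
# noise scaled to the configured sd, emulating residual sample-level bias
# that survives GC correction in real ULP-WGS libraries.
sample_bias_wave <- function(nb, sd, scale) {
  if (sd <= 0) return(rep(0, nb))
  k <- max(1L, as.integer(scale))
  z <- stats::rnorm(nb + 2L * k)
  w <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
  w <- w[(k + 1L):(k + nb)]
  w[is.na(w)] <- 0
  w * sd / max(stats::sd(w), 1e-12)
}

# Multiplicative per-bin placement weight from technical biases.
bias_weights <- function(grid, gc_bias_strength, wave = NULL) {
  b <- grid$bins
  w <- 2^(gc_bias_strength * (b$gc - 0.45)) * b$mappability
  if (!is.null(wave)) w <- w * 2^wave
  w
}

#' Simulate cfDNA fragments for one sample
#'
#' Forward model of the two-component mixture the tumor-fraction estimator
#' inverts: a fragment is tumor-derived with probability proportional to
#' `tf * c(bin) / 2` against `(1 - tf)` for the normal component, its bin is
#' drawn with weight origin-copy-number x GC-bias x mappability (x an
#' optional per-sample coverage wave), and its length comes from the
#' origin's component of the length model.
#'
#' @param grid A `genome_grid`.
#' @param events CNA event `data.frame` (may be empty).
#' @param tf True tumor fraction in `[0, 1)`.
#' @param n Number of fragments.
#' @param length_model Length model list (see [default_sim_config()]).
#' @param seed Integer seed.
#' @param gc_bias_strength log2-scale GC bias coefficient.
#' @param sample_bias Optional per-bin log2 wave (length `n_bins(grid)`).
#' @param sample_id Sample identifier stored on the records.
#' @return Fragment `data.frame` with an extra logical column `tumor_origin`
#'   (the generator truth, dropped by the IO layer).
#' @export
simulate_fragments <- function(grid, events, tf, n, length_model,
                               seed, gc_bias_strength = 0,
                               sample_bias = NULL, sample_id = "S1") {
  if (tf < 0 || tf >= 1) stop("tf must be in [0, 1)", call. = FALSE)
  stopifnot(n >= 1)
  cn <- bin_copy_number(grid, events)
  w <- bias_weights(grid, gc_bias_strength, sample_bias)
  nb <- n_bins(grid)
  w_tum <- tf * (cn / 2) * w
  w_nor <- (1 - tf) * w
  with_seed(seed, {
    pick <- sample.int(2L * nb, n, replace = TRUE, prob = c(w_nor, w_tum))
    tumor <- pick > nb
    bin <- ifelse(tumor, pick - nb, pick)
    b <- grid$bins[bin, ]
    len <- numeric(n)
    len[!tumor] <- draw_lengths(sum(!tumor), length_model, "healthy")
    len[tumor] <- draw_lengths(sum(tumor), length_model, "tumor")
    mid <- b$start + floor(stats::runif(n) * (b$end - b$start))
    start <- round(mid - len / 2)
    chrom_len <- grid$chromosomes$length[match(b$chrom, grid$chromosomes$name)]
    start <- pmax(0, pmin(start, chrom_len - len))
    data.frame(chrom = b$chrom, start = start, end = start + len,
               length = len, sample_id = sample_id, tumor_origin = tumor,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate per-bin counts directly (negative-binomial shortcut)
#'
#' Count for bin b is drawn from a negative binomial with mean
#' `mean_depth * ((1 - tf) * 2 + tf * c_b) / 2 * gcbias_b * mappability_b`
#' and the given dispersion (`size`); `dispersion = Inf` gives Poisson.
#'
#' @inheritParams simulate_fragments
#' @param mean_depth Expected count in a neutral, bias-free bin.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @return Integer vector of per-bin counts.
#' @export
simulate_bin_counts <- function(grid, events, tf, mean_depth, dispersion,
                                seed, gc_bias_strength = 0,
                                sample_bias = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (tf < 0 || tf >= 1) stop("tf must be in [0, 1)", call. = FALSE)
  cn <- bin_copy_number(grid, events)
  w <- bias_weights(grid, gc_bias_strength, sample_bias)
  mu <- mean_depth * ((1 - tf) * 2 + tf * cn) / 2 * w
  with_seed(seed, {
    if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = dispersion)
  })
}

# Serial tf trajectory multipliers for k timepoints.
trajectory_multipliers <- function(shape, k) {
  t <- seq_len(k) - 1
  switch(shape,
         response = exp(-1.2 * t),
         relapse = c(1, 0.2, 0.05, 0.4, 1.2, 2.2)[seq_len(k)],
         progression = 1.6^t,
         stop("unknown trajectory shape: ", shape, call. = FALSE))
}

#' Simulate the full synthetic cohort
#'
#' Generates the toy genome, per-participant CNA profiles and tumor-fraction
#' trajectories, per-sample fragment sets (or bin counts), cohort metadata,
#' serial SLD imaging coupled to true tumor fraction, therapy-change days,
#' and a truth table for parameter-recovery tests. Healthy and PN
#' participants contribute one sample each; MPNST participants contribute
#' serial samples (average 3, maximum 6).
#'
#' @param config A [default_sim_config()] list.
#' @param level `"fragments"` (full forward model) or `"counts"`
#'   (negative-binomial shortcut).
#' @return List with `grid`, `fragments` (named list, fragment level) or
#'   `counts` (bins x samples matrix), `meta`, `sld`, `therapy`, `truth`,
#'   `events` (per participant), `config`.
#' @export
simulate_cohort <- function(config = default_sim_config(),
                            level = c("fragments", "counts")) {
  level <- match.arg(level)
  if (is.null(config$seed)) stop("config must carry a seed", call. = FALSE)
  seed <- config$seed
  grid <- build_toy_genome(config, seed = stage_seed(seed, "genome"))
  nb <- n_bins(grid)

  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(config$n_healthy +
                                                config$n_pn + config$n_mpnst)),
    cohort = rep(c("HEALTHY", "PN", "MPNST"),
                 c(config$n_healthy, config$n_pn, config$n_mpnst)),
    stringsAsFactors = FALSE)

  meta <- list(); sld <- list(); therapy <- list(); truth <- list()
  frags <- list(); counts <- list(); events_by_p <- list()

  # serial draw counts for MPNST participants: permuted fixed multiset at
  # the study size, otherwise weighted draws on 1..6
  mpnst_ids <- participants$participant_id[participants$cohort == "MPNST"]
  serial_k <- with_seed(stage_seed(seed, "serial-design"), {
    ms <- config$serial_count_multiset
    if (!is.null(ms) && length(ms) == length(mpnst_ids)) sample(ms)
    else sample(1:6, length(mpnst_ids), replace = TRUE,
                prob = config$serial_count_probs)
  })
  names(serial_k) <- mpnst_ids

  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    cohort <- participants$cohort[i]
    pseed <- stage_seed(seed, paste0("participant:", pid))
    events <- sample_cna_profile(cohort, grid, pseed, config)
    events_by_p[[pid]] <- events

    pdat <- with_seed(stage_seed(seed, paste0("design:", pid)), {
      if (cohort == "MPNST") {
        k <- serial_k[[pid]]
        base_tf <- stats::runif(1, config$mpnst_tf_range[1],
                                config$mpnst_tf_range[2])
        shape <- sample(names(config$trajectory_probs), 1,
                        prob = config$trajectory_probs)
        days <- cumsum(c(0, round(stats::runif(
          max(k - 1, 0), 0.6, 1.4) * config$serial_interval_days)))
        list(k = k, tf = pmin(0.95, base_tf * trajectory_multipliers(shape, k)),
             days = days, shape = shape,
             age = round(stats::runif(1, 18, 60)),
             sex = sample(c("F", "M"), 1),
             inst = sample(c("NCI", "WUSTL"), 1))
      } else {
        tf0 <- if (cohort == "PN") config$pn_tf else config$healthy_tf
        list(k = 1L, tf = tf0, days = 0L, shape = "flat",
             age = round(stats::runif(1, 18, 60)),
             sex = sample(c("F", "M"), 1),
             inst = sample(c("NCI", "WUSTL"), 1))
      }
    })

    # therapy: MPNST participants with >1 sample start treatment shortly
    # after the baseline draw
    tdays <- integer(0)
    if (cohort == "MPNST" && pdat$k > 1L)
      tdays <- pdat$days[2] - 10L
    if (length(tdays)) therapy[[pid]] <- data.frame(
      participant_id = pid, day = tdays, stringsAsFactors = FALSE)

    for (t in seq_len(pdat$k)) {
      sid <- sprintf("%s_T%d", pid, t)
      day <- pdat$days[t]
      state <- if (t == 1L) "PRETREATMENT" else {
        since <- day - max(tdays[tdays <= day], -Inf)
        if (is.finite(since) && since < 21) "ON_TREATMENT" else "WASHOUT"
      }
      meta[[sid]] <- data.frame(
        sample_id = sid, participant_id = pid, cohort = cohort, day = day,
        treatment_state = state, age = pdat$age, sex = pdat$sex,
        institution = pdat$inst, stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(
        sample_id = sid, participant_id = pid, cohort = cohort, day = day,
        true_tf = pdat$tf[t], n_events = nrow(events),
        trajectory = pdat$shape, stringsAsFactors = FALSE)

      sseed <- stage_seed(seed, paste0("sample:", sid))
      wave <- with_seed(stage_seed(seed, paste0("wave:", sid)),
                        sample_bias_wave(nb, config$sample_bias_sd,
                                         config$sample_bias_scale))
      if (level == "fragments") {
        frags[[sid]] <- simulate_fragments(
          grid, events, pdat$tf[t], config$fragments_per_sample,
          config$length_model, sseed, config$gc_bias_strength, wave, sid)
      } else {
        counts[[sid]] <- simulate_bin_counts(
          grid, events, pdat$tf[t], config$mean_depth, config$dispersion,
          sseed, config$gc_bias_strength, wave)
      }
    }

    if (cohort == "MPNST") {
      sld[[pid]] <- with_seed(stage_seed(seed, paste0("sld:", pid)), {
        jit <- round(stats::runif(pdat$k, -config$sld_day_jitter,
                                  config$sld_day_jitter))
        d <- pdat$days + jit
        d <- d - min(d[1], 0)           # keep first observation >= 0
        d <- cummax(d + seq_len(pdat$k) * 0L)  # enforce non-decreasing
        d <- d + cumsum(c(0, diff(d) == 0))    # strictly increasing
        s <- pmax(0, config$sld_intercept + config$sld_slope * pdat$tf +
                    stats::rnorm(pdat$k, 0, config$sld_noise_sd))
        base <- s[1]
        recist <- ifelse(s == 0, "CR",
                         ifelse(s >= 1.2 * base, "PD",
                                ifelse(s <= 0.7 * base, "PR", "SD")))
        recist[1] <- "NONE"
        data.frame(participant_id = pid, day = d, sld = s,
                   recist = recist, stringsAsFactors = FALSE)
      })
    }
  }

  out <- list(grid = grid,
              meta = do.call(rbind, c(meta, make.row.names = FALSE)),
              sld = if (length(sld))
                do.call(rbind, c(sld, make.row.names = FALSE)) else NULL,
              therapy = if (length(therapy))
                do.call(rbind, c(therapy, make.row.names = FALSE)) else NULL,
              truth = do.call(rbind, c(truth, make.row.names = FALSE)),
              events = events_by_p, config = config)
  if (level == "fragments") out$fragments <- frags
  else out$counts <- do.call(cbind, counts)
  out
}
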