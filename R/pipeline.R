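#' Estimate tumor fractions across a simulated cohort
#'
#' Runs the per-sample copy-number pipeline over a fragment-level cohort:
#' optional in silico size selection, midpoint binning, GC/mappability
#' correction, panel-of-normals normalization against the healthy cohort,
#' and mixture-HMM tumor-fraction fitting.
#'
#' @param cohort Output of [simulate_cohort()] at `level = "fragments"`.
#' @param size_selected Apply the 90-150 bp window first (default TRUE).
#' @param lo_bp,hi_bp Selection bounds.
#' @param params [mixture_hmm_params()] for the fits.
#' @param mad_cap Panel MAD mask threshold.
#' @return List: `tf_table` (`data.frame` with `sample_id`, `tf`,
#'   `detected`, `converged`), `lrs` (named list of `corrected_lr`),
#'   `panel_ids`.
#' @export
estimate_cohort_tf <- function(cohort, size_selected = TRUE, lo_bp = 90,
                               hi_bp = 150, params = mixture_hmm_params(),
                               mad_cap = 0.2) {
  grid <- cohort$grid
  prep <- function(fr) {
    if (size_selected) fr <- size_select(fr, lo_bp, hi_bp)
    correct_bias(bin_counts(fr, grid), grid)
  }
  raw_lrs <- lapply(cohort$fragments, prep)
  panel_ids <- cohort$meta$sample_id[cohort$meta$cohort == "HEALTHY"]
  panel <- raw_lrs[panel_ids]
  lrs <- lapply(names(raw_lrs), function(sid) {
    # leave the sample out of its own panel
    p <- panel[setdiff(panel_ids, sid)]
    panel_normalize(raw_lrs[[sid]], p, mad_cap = mad_cap)
  })
  names(lrs) <- names(raw_lrs)
  fits <- lapply(lrs, fit_tumor_fraction, grid = grid, params = params)
  tf_table <- data.frame(
    sample_id = names(fits),
    tf = vapply(fits, `[[`, numeric(1), "tf"),
    detected = vapply(fits, `[[`, logical(1), "detected"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tf_table = tf_table, lrs = lrs, panel_ids = panel_ids)
}

#' Select baseline (pretreatment) samples for the primary comparison
#'
#' MPNST samples qualify when drawn before any treatment or after a washout
#' of at least 21 days (treatment_state PRETREATMENT or WASHOUT); healthy
#' and PN samples always qualify. One sample per participant: the earliest
#' qualifying one in `"pretreatment"` mode, or the participant's maximum
#' tumor fraction over qualifying samples in `"serial_max"` mode.
#'
#' @param tf_table `data.frame` with `sample_id`, `tf`.
#' @param meta Metadata `data.frame` (see [read_metadata()]).
#' @param mode `"pretreatment"` or `"serial_max"`.
#' @return Per-participant `data.frame` with `participant_id`, `cohort`,
#'   `tf`, `age`, `sex`, `institution`.
#' @export
participant_tf <- function(tf_table, meta,
                           mode = c("pretreatment", "serial_max")) {
  mode <- match.arg(mode)
  m <- merge(meta, tf_table, by = "sample_id")
  ok <- m$cohort != "MPNST" |
    m$treatment_state %in% c("PRETREATMENT", "WASHOUT")
  m <- m[ok, ]
  out <- lapply(split(m, m$participant_id), function(d) {
    d <- d[order(d$day), ]
    row <- if (mode == "pretreatment") d[1, ] else d[which.max(d$tf), ]
    row[, c("participant_id", "cohort", "tf", "age", "sex", "institution")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id), ]
}

#' Classification report: MPNST versus PN from plasma tumor fraction
#'
#' Kruskal-Wallis/Dunn across the three cohorts, ROC with Youden cutpoint
#' for MPNST vs PN, cutpoint classification with Fisher exact test, LOOCV
#' penalized logistic accuracy, and multivariate logistic regression of
#' status on tumor fraction plus age, sex and institution.
#'
#' @param ptf Output of [participant_tf()].
#' @param seed Seed for LOOCV inner folds.
#' @return Named list with `kruskal`, `roc` (auc, cutpoint, J),
#'   `classification`, `loocv`, `logistic`.
#' @export
classify_report <- function(ptf, seed = 1L) {
  groups <- split(ptf$tf, ptf$cohort)[c("HEALTHY", "PN", "MPNST")]
  kw <- kruskal_dunn(groups)
  mp <- ptf[ptf$cohort %in% c("MPNST", "PN"), ]
  lab <- mp$cohort == "MPNST"
  rc <- roc(mp$tf, lab)
  cut <- youden_cutpoint(rc)
  cls <- classify_and_test(mp$tf, lab, cut)
  lo <- loocv_logistic(matrix(mp$tf, ncol = 1,
                              dimnames = list(NULL, "tf")), lab,
                       seed = seed)
  covs <- data.frame(age = mp$age, sex = factor(mp$sex),
                     institution = factor(mp$institution))
  ml <- multivariate_logistic(lab, mp$tf, covs)
  list(kruskal = kw,
       roc = list(auc = rc$auc, cutpoint = cut, youden_J = rc$youden_J,
                  curve = data.frame(threshold = rc$thresholds,
                                     sensitivity = rc$sensitivity,
                                     specificity = rc$specificity)),
       classification = cls, loocv = lo[c("accuracy", "ci")],
       logistic = ml[c("coefficients", "separation", "rank_deficient")])
}

#' Assemble serial timelines for monitored participants
#'
#' @param tf_table Per-sample tumor fractions (`sample_id`, `tf`,
#'   `detected`).
#' @param meta Metadata table.
#' @param sld SLD table (see [read_sld()]), may be NULL.
#' @param therapy `data.frame` with `participant_id`, `day`, may be NULL.
#' @param min_samples Keep participants with at least this many plasma
#'   samples (default 2).
#' @return Named list of `serial_timeline` objects.
#' @export
build_timelines <- function(tf_table, meta, sld = NULL, therapy = NULL,
                            min_samples = 2L) {
  m <- merge(meta, tf_table, by = "sample_id")
  m <- m[m$cohort == "MPNST", ]
  out <- list()
  for (pid in unique(m$participant_id)) {
    d <- m[m$participant_id == pid, ]
    if (nrow(d) < min_samples) next
    d <- d[order(d$day), ]
    s <- if (!is.null(sld)) sld[sld$participant_id == pid, ] else NULL
    tcd <- if (!is.null(therapy))
      therapy$day[therapy$participant_id == pid] else integer(0)
    out[[pid]] <- serial_timeline(
      pid, data.frame(day = d$day, tf = d$tf, detected = d$detected),
      s, tcd)
  }
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> fragmentomics -> binning/bias correction -> tumor fraction
#' (with and without size selection) -> classification -> serial
#' monitoring, writing a versioned report bundle. Every output embeds the
#' config hash and global seed; a fixed seed makes the whole bundle
#' byte-identical across runs.
#'
#' @param config [default_sim_config()]; must carry a seed unless
#'   `global_seed` is given.
#' @param out_dir Output directory (created).
#' @param global_seed Overrides `config$seed`.
#' @return The report list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = default_sim_config(), out_dir,
                         global_seed = config$seed) {
  if (is.null(global_seed)) stop("a seed is required", call. = FALSE)
  config$seed <- as.integer(global_seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(unclass(config))

  cohort <- simulate_cohort(config, level = "fragments")
  meta <- cohort$meta

  # fragmentomics: pooled MPNST vs PN fragment lengths
  pool <- function(coh) {
    ids <- meta$sample_id[meta$cohort == coh]
    unlist(lapply(cohort$fragments[ids], `[[`, "length"), use.names = FALSE)
  }
  len_m <- pool("MPNST"); len_p <- pool("PN")
  ks <- ks_two_sample(len_m, len_p)

  sel <- estimate_cohort_tf(cohort, size_selected = TRUE)
  uns <- estimate_cohort_tf(cohort, size_selected = FALSE)

  ptf_sel <- participant_tf(sel$tf_table, meta, "pretreatment")
  ptf_uns <- participant_tf(uns$tf_table, meta, "pretreatment")
  rep_sel <- classify_report(ptf_sel, seed = stage_seed(global_seed, "loocv"))
  mp_uns <- ptf_uns[ptf_uns$cohort %in% c("MPNST", "PN"), ]
  auc_uns <- roc(mp_uns$tf, mp_uns$cohort == "MPNST")$auc

  tls <- build_timelines(sel$tf_table, meta, cohort$sld, cohort$therapy)
  pairs <- do.call(rbind, c(lapply(tls, match_sld_tf),
                            make.row.names = FALSE))
  corr <- if (!is.null(pairs) && nrow(pairs) >= 3) correlate(pairs) else NULL
  leads <- lapply(tls, lead_time)
  leads <- leads[!vapply(leads, is.null, logical(1))]

  tf_tab <- merge(merge(sel$tf_table, cohort$truth[, c("sample_id",
                                                       "true_tf")],
                        by = "sample_id"),
                  stats::setNames(uns$tf_table[, c("sample_id", "tf")],
                                  c("sample_id", "tf_unselected")),
                  by = "sample_id")
  tf_tab <- tf_tab[order(tf_tab$sample_id), ]

  report <- list(
    version = "1", config_hash = chash, seed = as.integer(global_seed),
    fragmentomics = list(ks_D = ks$D, ks_p = ks$p_value,
                         n_mpnst = ks$n1, n_pn = ks$n2),
    classification = list(
      auc_size_selected = rep_sel$roc$auc, auc_unselected = auc_uns,
      cutpoint = rep_sel$roc$cutpoint,
      sensitivity = rep_sel$classification$sensitivity$estimate,
      specificity = rep_sel$classification$specificity$estimate,
      fisher_p = rep_sel$classification$fisher_p,
      loocv_accuracy = rep_sel$loocv$accuracy,
      kruskal_p = rep_sel$kruskal$p_value),
    monitoring = list(
      n_matched_pairs = if (is.null(pairs)) 0L else nrow(pairs),
      pearson_r = if (is.null(corr)) NA else corr$r,
      pearson_p = if (is.null(corr)) NA else corr$p_value,
      lead_times = leads))

  hdr <- sprintf("# config_hash=%s seed=%d", chash, as.integer(global_seed))
  write_tsv_stamped <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  write_tsv_stamped(tf_tab, file.path(out_dir, "tf_table.tsv"))
  write_tsv_stamped(meta, file.path(out_dir, "metadata.tsv"))
  if (!is.null(cohort$sld))
    write_tsv_stamped(cohort$sld, file.path(out_dir, "sld.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
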