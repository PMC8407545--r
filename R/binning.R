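#' Count fragments in genome bins
#'
#' Each fragment is assigned to exactly one bin by its midpoint, so
#' fragments straddling a bin edge are not double-counted. Fragments on a
#' chromosome absent from the grid are an error.
#'
#' @param fragments Fragment `data.frame`.
#' @param grid A `genome_grid`.
#' @return Object of class `binned_coverage`: list with `counts` (per-bin
#'   integers), `n_fragments`, `sample_id`.
#' @export
bin_counts <- function(fragments, grid) {
  if (nrow(fragments) == 0L)
    return(structure(list(counts = rep(0L, n_bins(grid)),
                          n_fragments = 0L, sample_id = NA_character_),
                     class = "binned_coverage"))
  mid <- floor((fragments$start + fragments$end) / 2)
  idx <- bin_index(grid, fragments$chrom, mid)
  counts <- tabulate(idx, nbins = n_bins(grid))
  structure(list(counts = counts, n_fragments = nrow(fragments),
                 sample_id = fragments$sample_id[1]),
            class = "binned_coverage")
}

#' GC and mappability bias correction of binned counts
#'
#' Pipeline: (1) mask bins that are sex-chromosomal, have mappability below
#' `map_min`, or have zero count; (2) LOESS fit of log2 count against GC
#' over unmasked bins, subtracted on the log scale; (3) division by
#' mappability; (4) log2 ratio against the sample median, re-centered so the
#' unmasked median is exactly 0 (a majority-neutral genome is assumed).
#'
#' @param counts Integer per-bin counts or a `binned_coverage`.
#' @param grid A `genome_grid`.
#' @param map_min Mappability mask threshold (default 0.9).
#' @param loess_span LOESS span for the GC curve (default 0.3), fitted with
#'   symmetric (robust) weights.
#' @param min_bins Minimum unmasked bins required (default 50).
#' @return Object of class `corrected_lr`: list with `log2_ratio` (NA on
#'   masked bins), `mask`, `report` (gc curve summary, mask counts).
#' @export
correct_bias <- function(counts, grid, map_min = 0.9, loess_span = 0.3,
                         min_bins = 50) {
  if (inherits(counts, "binned_coverage")) counts <- counts$counts
  stopifnot(length(counts) == n_bins(grid))
  if (all(counts == 0)) stop("all bin counts are zero", call. = FALSE)
  b <- grid$bins
  mask <- b$mask | b$mappability < map_min | counts == 0
  if (sum(!mask) < min_bins)
    stop("fewer than ", min_bins, " unmasked bins", call. = FALSE)
  gc <- b$gc[!mask]
  y <- log2(counts[!mask])
  if (stats::sd(gc) < 1e-6) {
    # degenerate GC track (e.g. uniform synthetic grids): flat curve
    fitted_curve <- rep(stats::median(y), length(y))
  } else {
    fit <- stats::loess(y ~ gc, span = loess_span, degree = 2,
                        family = "symmetric",
                        control = stats::loess.control(iterations = 2,
                                                       surface = "direct"))
    fitted_curve <- stats::predict(fit, gc)
  }
  resid <- y - fitted_curve
  v <- 2^resid / b$mappability[!mask]
  lr <- log2(v / stats::median(v))
  lr <- lr - stats::median(lr)
  out <- rep(NA_real_, length(counts))
  out[!mask] <- lr
  structure(list(
    log2_ratio = out, mask = mask,
    report = list(gc_curve = stats::quantile(fitted_curve, c(0.05, 0.5, 0.95)),
      n_masked_mappability = sum(b$mappability < map_min & !b$mask),
      n_masked_zero = sum(counts == 0 & !b$mask),
      n_unmasked = sum(!mask))),
    class = "corrected_lr")
}

#' Panel-of-normals normalization
#'
#' Subtracts the per-bin median log2 ratio of a healthy reference panel,
#' removing recurrent technical artifacts; bins whose panel median absolute
#' deviation exceeds `mad_cap` (unstable in normals) are masked. The result
#' is re-centered to unmasked median 0.
#'
#' @param sample_lr A `corrected_lr`.
#' @param panel List of >= 3 `corrected_lr` objects on the same grid.
#' @param mad_cap Panel MAD masking threshold (default 0.2, log2 units).
#' @return A `corrected_lr` with panel information in `report`.
#' @export
panel_normalize <- function(sample_lr, panel, mad_cap = 0.2) {
  if (length(panel) < 3L) stop("panel needs >= 3 samples", call. = FALSE)
  nb <- length(sample_lr$log2_ratio)
  if (any(vapply(panel, function(p) length(p$log2_ratio), 1L) != nb))
    stop("panel grid mismatch", call. = FALSE)
  pm <- do.call(cbind, lapply(panel, `[[`, "log2_ratio"))
  med <- apply(pm, 1, stats::median, na.rm = TRUE)
  madv <- apply(pm, 1, stats::mad, na.rm = TRUE)
  lr <- sample_lr$log2_ratio - med
  mask <- sample_lr$mask | is.na(med) | (!is.na(madv) & madv > mad_cap)
  lr[mask] <- NA_real_
  lr <- lr - stats::median(lr, na.rm = TRUE)
  structure(list(log2_ratio = lr, mask = mask,
                 report = c(sample_lr$report,
                            list(panel_n = length(panel),
                                 n_masked_panel_mad = sum(
                                   !sample_lr$mask & !is.na(madv) &
                                     madv > mad_cap)))),
            class = "corrected_lr")
}

#' Threshold gain/loss calls on a log2 ratio profile
#'
#' A bin is a GAIN if its log2 copy-number ratio exceeds 0.58 (log2(3/2))
#' and a LOSS if it is below -1.0 (log2(1/2)); both inequalities are strict.
#' Masked bins propagate as MASKED.
#'
#' @param lr A `corrected_lr` or numeric log2-ratio vector (NA = masked).
#' @param gain,loss Thresholds (defaults 0.58 and -1.0).
#' @return Character vector of per-bin labels in
#'   `{GAIN, NEUTRAL, LOSS, MASKED}`.
#' @export
threshold_call <- function(lr, gain = 0.58, loss = -1.0) {
  x <- if (inherits(lr, "corrected_lr")) lr$log2_ratio else lr
  out <- rep("NEUTRAL", length(x))
  out[!is.na(x) & x > gain] <- "GAIN"
  out[!is.na(x) & x < loss] <- "LOSS"
  out[is.na(x)] <- "MASKED"
  out
}

#' Aggregate per-bin profiles across a cohort
#'
#' Per-bin mean log2 ratio and gain/loss call frequencies over a set of
#' samples (one cohort), for genome-wide compiled CNA plots.
#'
#' @param lr_list List of `corrected_lr` objects on a shared grid.
#' @param grid The `genome_grid`.
#' @param gain,loss Thresholds passed to [threshold_call()].
#' @return `data.frame` with `chrom`, `start`, `end`, `mean_log2_ratio`,
#'   `gain_freq`, `loss_freq`, `n` (samples informative per bin).
#' @export
aggregate_cohort <- function(lr_list, grid, gain = 0.58, loss = -1.0) {
  if (length(lr_list) == 0L) stop("empty cohort", call. = FALSE)
  m <- do.call(cbind, lapply(lr_list, `[[`, "log2_ratio"))
  calls <- apply(m, 2, threshold_call, gain = gain, loss = loss)
  n_inf <- rowSums(!is.na(m))
  data.frame(grid$bins[, c("chrom", "start", "end")],
             mean_log2_ratio = rowMeans(m, na.rm = TRUE),
             gain_freq = rowSums(calls == "GAIN") / pmax(n_inf, 1L),
             loss_freq = rowSums(calls == "LOSS") / pmax(n_inf, 1L),
             n = n_inf, row.names = NULL)
}
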