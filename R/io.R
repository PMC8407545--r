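#' Read cfDNA fragment records from a BED-like file
#'
#' Expects a tab-separated file with columns `chrom`, `start`, `end` and an
#' optional fourth `sample_id` column, no header, 0-based half-open
#' coordinates. Fragment length is `end - start` (the sequenced template's
#' outer distance). Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @param sample_id Sample identifier applied when the file has no fourth
#'   column (default `NA`).
#' @return `data.frame` with `chrom`, `start`, `end`, `length`, `sample_id`,
#'   in file order.
#' @export
read_fragments <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) return(empty_fragments())
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) return(empty_fragments())
  if (ncol(raw) < 3L)
    stop("fragment file needs >= 3 tab-separated columns", call. = FALSE)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("non-integer coordinates at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop("end <= start at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  sid <- if (ncol(raw) >= 4L) raw[[4]] else rep(sample_id, nrow(raw))
  data.frame(chrom = raw[[1]], start = start, end = end,
             length = end - start, sample_id = sid,
             stringsAsFactors = FALSE)
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             length = numeric(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Write fragment records as a BED-like TSV
#' @param fragments Fragment `data.frame` (see [read_fragments()]).
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(
    fragments[, c("chrom", "start", "end", "sample_id")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bin copy-number profile as SEG
#'
#' Adjacent bins in the same copy-number state are merged into one segment.
#' Internal 0-based half-open bin coordinates are converted to the SEG
#' convention (1-based inclusive). Masked bins break segments and are not
#' emitted.
#'
#' @param profile `data.frame` with `chrom`, `start`, `end`, `state`
#'   (integer copy number or `NA` for masked) and `log2_ratio`, sorted in
#'   genome order.
#' @param path Output path.
#' @param sample_id Sample column value.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profile, path, sample_id = "sample") {
  stopifnot(all(c("chrom", "start", "end", "state", "log2_ratio")
                %in% names(profile)))
  keep <- !is.na(profile$state)
  rows <- list()
  if (any(keep)) {
    p <- profile[keep, , drop = FALSE]
    # run id changes when chrom or state changes
    brk <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)] |
               p$state[-1] != p$state[-nrow(p)] |
               p$start[-1] != p$end[-nrow(p)])
    run <- cumsum(brk)
    rows <- lapply(split(seq_len(nrow(p)), run), function(i) {
      data.frame(sample = sample_id, chrom = p$chrom[i[1]],
                 start = p$start[i[1]] + 1, end = p$end[i[length(i)]],
                 num_bins = length(i),
                 seg_mean = mean(p$log2_ratio[i]),
                 state = p$state[i[1]], stringsAsFactors = FALSE)
    })
  }
  seg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), num_bins = integer(), seg_mean = numeric(),
               state = integer())
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file back to per-segment rows
#' @param path SEG path written by [write_seg()].
#' @return `data.frame` of segments with 1-based inclusive coordinates.
#' @export
read_seg <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

cohort_levels <- c("HEALTHY", "PN", "MPNST")
treatment_levels <- c("PRETREATMENT", "ON_TREATMENT", "WASHOUT")
recist_levels <- c("CR", "PR", "SD", "PD", "NONE")

#' Read the cohort metadata table
#'
#' TSV with header columns `sample_id`, `participant_id`, `cohort`, `day`,
#' `treatment_state`, `age`, `sex`, `institution`. Unknown cohort or
#' treatment labels and duplicate sample ids are rejected.
#'
#' @param path File path.
#' @return Validated `data.frame`.
#' @export
read_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_id", "cohort", "day",
            "treatment_state", "age", "sex", "institution")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- setdiff(unique(m$cohort), cohort_levels)
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(m$treatment_state), treatment_levels)
  if (length(bad))
    stop("unknown treatment_state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  m
}

#' Check washout states against therapy-change days
#'
#' A sample labeled WASHOUT must have been drawn at least `min_days` (21)
#' days after the participant's most recent therapy change, when
#' therapy-change days are available.
#'
#' @param meta Metadata `data.frame` (see [read_metadata()]).
#' @param therapy `data.frame` with `participant_id`, `day`.
#' @param min_days Minimum washout in days (default 21).
#' @return `meta`, invisibly; errors on a violation.
#' @export
validate_washout <- function(meta, therapy, min_days = 21) {
  w <- meta[meta$treatment_state == "WASHOUT", ]
  for (i in seq_len(nrow(w))) {
    td <- therapy$day[therapy$participant_id == w$participant_id[i] &
                        therapy$day <= w$day[i]]
    if (length(td) && w$day[i] - max(td) < min_days)
      stop("sample ", w$sample_id[i], " labeled WASHOUT only ",
           w$day[i] - max(td), " days after a therapy change",
           call. = FALSE)
  }
  invisible(meta)
}

#' Read the serial imaging (SLD) table
#'
#' TSV with header columns `participant_id`, `day`, `sld` (cm), `recist`.
#' Days must be strictly increasing within a participant; SLD must be
#' finite and non-negative; RECIST labels are restricted to
#' CR/PR/SD/PD/NONE.
#'
#' @param path File path.
#' @return Validated `data.frame`.
#' @export
read_sld <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "sld", "recist")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("SLD table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(s$sld) | s$sld < 0))
    stop("SLD values must be finite and >= 0", call. = FALSE)
  bad <- setdiff(unique(s$recist), recist_levels)
  if (length(bad))
    stop("unknown RECIST label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (pid in unique(s$participant_id)) {
    d <- s$day[s$participant_id == pid]
    if (any(diff(d) <= 0))
      stop("days not strictly increasing for participant ", pid,
           call. = FALSE)
  }
  s
}

#' Write / read a genome grid as TSV
#'
#' One row per bin (`chrom`, `start`, `end`, `gc`, `mappability`); the
#' reader reconstructs the `genome_grid` (chromosome lengths from the last
#' bin end, bin width from the modal bin size).
#'
#' @param grid A `genome_grid`.
#' @param path File path.
#' @return `path` (writer) or a `genome_grid` (reader).
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$bins[, c("chrom", "start", "end", "gc",
                                   "mappability")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  chroms <- do.call(rbind, lapply(split(b, factor(b$chrom,
                                                  unique(b$chrom))),
                                  function(d) data.frame(
                                    name = d$chrom[1], length = max(d$end),
                                    stringsAsFactors = FALSE)))
  rownames(chroms) <- NULL
  widths <- b$end - b$start
  bw <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
  genome_grid(chroms, bw, gc = b$gc, mappability = b$mappability)
}

#' Write / read the per-bin table
#'
#' The bin table is the pipeline's central on-disk format: one row per bin
#' with `chrom`, `start`, `end`, `gc`, `mappability`, `count`, `log2_ratio`,
#' `state` (any of the last three may be absent depending on stage).
#'
#' @param bins Bin `data.frame`.
#' @param path File path.
#' @return `path` (writer) or the `data.frame` (reader).
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
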