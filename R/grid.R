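#' Genome grid: fixed-width bins with GC and mappability
#'
#' A `genome_grid` holds an ordered set of chromosomes tiled by fixed-width
#' bins (the last bin of a chromosome may be shorter), each carrying a GC
#' fraction and a mappability score, plus a per-bin analysis mask. All
#' internal coordinates are 0-based half-open, matching BED fragment input.
#' Sex chromosomes (names matching `chrX`/`chrY`/`X`/`Y`) are always masked:
#' they are excluded from copy-number ratios.
#'
#' @param chromosomes `data.frame` with columns `name`, `length` (bp).
#' @param bin_width Bin width in bp (default 1e6).
#' @param gc Optional per-bin GC fractions in `[0, 1]` (recycled check only).
#' @param mappability Optional per-bin mappability in `[0, 1]`.
#' @return An object of class `genome_grid`: a list with `chromosomes`,
#'   `bin_width`, and `bins` (a `data.frame` with `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `mask`).
#' @export
genome_grid <- function(chromosomes, bin_width = 1e6, gc = NULL,
                        mappability = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names", call. = FALSE)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  if (bin_width > min(chromosomes$length))
    stop("bin_width exceeds the shortest chromosome", call. = FALSE)

  per <- lapply(seq_len(nrow(chromosomes)), function(i) {
    len <- chromosomes$length[i]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = chromosomes$name[i], start = starts,
               end = pmin(starts + bin_width, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per)
  n <- nrow(bins)
  if (is.null(gc)) gc <- rep(0.45, n)
  if (is.null(mappability)) mappability <- rep(1, n)
  stopifnot(length(gc) == n, length(mappability) == n)
  if (!all(is.finite(gc)) || any(gc < 0 | gc > 1))
    stop("gc fractions must be finite and in [0, 1]", call. = FALSE)
  if (!all(is.finite(mappability)) || any(mappability < 0 | mappability > 1))
    stop("mappability must be finite and in [0, 1]", call. = FALSE)
  bins$gc <- gc
  bins$mappability <- mappability
  bins$mask <- is_sex_chrom(bins$chrom)
  structure(list(chromosomes = chromosomes, bin_width = bin_width,
                 bins = bins),
            class = "genome_grid")
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom)) %in% c("X", "Y")
}

#' @export
print.genome_grid <- function(x, ...) {
  cat(sprintf("genome_grid: %d chromosomes, %d bins of %s bp (%d masked)\n",
              nrow(x$chromosomes), nrow(x$bins),
              format(x$bin_width, big.mark = ","), sum(x$bins$mask)))
  invisible(x)
}

#' Number of bins in a grid
#' @param grid A `genome_grid`.
#' @return Integer bin count.
#' @export
n_bins <- function(grid) nrow(grid$bins)

# Map genomic positions to bin indices (0-based positions). Exploits the
# fixed-width tiling: index = chromosome offset + pos %/% bin_width.
# Positions on unknown chromosomes raise an error naming the chromosome.
bin_index <- function(grid, chrom, pos) {
  ci <- match(chrom, grid$chromosomes$name)
  if (anyNA(ci))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(ci)]), collapse = ", "), call. = FALSE)
  if (any(pos < 0 | pos >= grid$chromosomes$length[ci]))
    stop("position outside chromosome bounds", call. = FALSE)
  nb_per <- ceiling(grid$chromosomes$length / grid$bin_width)
  offset <- c(0, cumsum(nb_per))
  as.integer(offset[ci] + pos %/% grid$bin_width + 1)
}

# Per-bin tumor copy number implied by a CNA event table (neutral = 2).
# Events are applied to every bin whose midpoint lies within the event.
bin_copy_number <- function(grid, events) {
  cn <- rep(2L, n_bins(grid))
  if (is.null(events) || nrow(events) == 0L) return(cn)
  mid <- (grid$bins$start + grid$bins$end) / 2
  for (i in seq_len(nrow(events))) {
    hit <- grid$bins$chrom == events$chrom[i] &
      mid >= events$start[i] & mid < events$end[i]
    cn[hit] <- as.integer(events$copy_number[i])
  }
  cn
}
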