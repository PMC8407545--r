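#' In silico fragment size selection
#'
#' Retains fragments whose length lies in the inclusive window
#' `[lo_bp, hi_bp]`, the computational enrichment step for circulating tumor
#' DNA: tumor-derived cfDNA runs shorter than the mono-nucleosomal
#' background, so the 90-150 bp window raises the tumor-derived proportion
#' of what remains. Input order is preserved and the operation is
#' idempotent.
#'
#' @param fragments Fragment `data.frame` with a `length` column.
#' @param lo_bp,hi_bp Inclusive bounds in bp (defaults 90 and 150).
#' @return The filtered `data.frame`.
#' @export
size_select <- function(fragments, lo_bp = 90, hi_bp = 150) {
  if (lo_bp >= hi_bp) stop("lo_bp must be < hi_bp", call. = FALSE)
  fragments[fragments$length >= lo_bp & fragments$length <= hi_bp, ,
            drop = FALSE]
}

#' Downsample fragments without replacement
#'
#' @param fragments Fragment `data.frame`.
#' @param n_target Target count; if `n_target >= nrow(fragments)` the input
#'   is returned unchanged.
#' @param seed Integer seed.
#' @return Uniform random subset in original row order.
#' @export
downsample <- function(fragments, n_target, seed) {
  if (n_target < 0) stop("n_target must be >= 0", call. = FALSE)
  n <- nrow(fragments)
  if (n_target >= n) return(fragments)
  keep <- with_seed(seed, sort(sample.int(n, n_target)))
  fragments[keep, , drop = FALSE]
}

#' Gaussian kernel density of fragment lengths
#'
#' @param fragments Fragment `data.frame` (>= 2 rows) or numeric lengths.
#' @param bandwidth Kernel bandwidth in bp; default Silverman's rule
#'   (`stats::bw.nrd0`) on the sample.
#' @param grid Ordered bp values at which to evaluate; default `60:450`.
#' @return List of class `length_density`: `grid`, `density` (trapezoid
#'   normalized to integrate to 1 over `grid`), `bandwidth`, `n`.
#' @export
length_density <- function(fragments, bandwidth = NULL, grid = 60:450) {
  len <- if (is.data.frame(fragments)) fragments$length else fragments
  if (length(len) < 2L) stop("need >= 2 fragments", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(len)
  d <- stats::density(len, bw = bandwidth, from = min(grid), to = max(grid),
                      n = 2048)
  y <- stats::approx(d$x, d$y, xout = grid, rule = 2)$y
  y <- pmax(y, 0)
  y <- y / trapz(grid, y)
  structure(list(grid = grid, density = y, bandwidth = bandwidth,
                 n = length(len)), class = "length_density")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs (exact under ties); the two-sided p-value uses the asymptotic
#' Kolmogorov distribution with the effective sample size
#' `n1 * n2 / (n1 + n2)`.
#'
#' @param lengths_a,lengths_b Numeric samples (nonempty).
#' @return List of class `ks_result`: `D`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(lengths_a, lengths_b) {
  n1 <- length(lengths_a); n2 <- length(lengths_b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty",
                                 call. = FALSE)
  pts <- sort(unique(c(lengths_a, lengths_b)))
  fa <- findInterval(pts, sort(lengths_a)) / n1
  fb <- findInterval(pts, sort(lengths_b)) / n2
  D <- max(abs(fa - fb))
  neff <- as.numeric(n1) * n2 / (as.numeric(n1) + n2)
  lambda <- max(sqrt(neff) * D, 0)
  # asymptotic two-sided Kolmogorov tail
  j <- 1:100
  p <- if (lambda < 1e-10) 1 else
    min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
  structure(list(D = D, p_value = p, n1 = n1, n2 = n2),
            class = "ks_result")
}

#' Log2 ratio of two length densities
#'
#' Densities are floored at `eps` before the ratio so sparsely supported
#' lengths do not produce infinities.
#'
#' @param density_a,density_b `length_density` objects on the same grid.
#' @param eps Density floor (default 1e-8).
#' @return Numeric vector `log2(pmax(a, eps) / pmax(b, eps))` on the grid.
#' @export
log2_density_ratio <- function(density_a, density_b, eps = 1e-8) {
  if (!identical(density_a$grid, density_b$grid))
    stop("density grids differ", call. = FALSE)
  log2(pmax(density_a$density, eps) / pmax(density_b$density, eps))
}
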