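#' Expected log2 copy-number ratio under the two-component mixture
#'
#' A plasma sample is modeled as a mixture of tumor-derived fragments
#' (fraction `tf`, local copy number `c`) and normal-derived fragments
#' (fraction `1 - tf`, diploid), so a bin's expected depth ratio against a
#' neutral genome is `(tf * c + (1 - tf) * 2) / 2` and its expected log2
#' ratio is the log2 of that. At `c = 3, tf = 1` this is log2(3/2) = 0.585,
#' the gain-call threshold's rationale; at `c = 1, tf = 1` it is -1.0.
#'
#' @param c Copy number (>= 0), vectorized.
#' @param tf Tumor fraction in `[0, 1]`.
#' @return log2 ratio(s).
#' @export
expected_log_ratio <- function(c, tf) {
  stopifnot(all(c >= 0), tf >= 0, tf <= 1)
  log2((tf * c + (1 - tf) * 2) / 2)
}

#' Parameters of the mixture/HMM tumor-fraction model
#'
#' @param states Tumor copy-number states; must include 2 (default 1:4).
#' @param self_transition Probability of staying in the same state between
#'   adjacent bins (default 0.9999); the remainder is spread uniformly.
#' @param emission_sd Initial Gaussian emission sd in log2 units (default
#'   0.15), re-estimated by EM.
#' @param tf_restarts Initial tumor-fraction values for EM restarts.
#' @param max_iter Maximum EM iterations per restart (default 50).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-4).
#' @param detection_floor Estimates below this are reported as not detected
#'   (default 0.03).
#' @param init_neutral Initial-state probability mass on the neutral state
#'   (default 0.9).
#' @return Named list of class `mixture_hmm_params`.
#' @export
mixture_hmm_params <- function(states = 1:4, self_transition = 0.9999,
                               emission_sd = 0.15,
                               tf_restarts = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                               max_iter = 50L, tol = 1e-4,
                               detection_floor = 0.03,
                               init_neutral = 0.9) {
  if (!2 %in% states) stop("states must include the neutral state 2",
                           call. = FALSE)
  stopifnot(self_transition > 0, self_transition < 1, tol > 0,
            emission_sd > 0)
  structure(list(states = sort(unique(as.integer(states))),
                 self_transition = self_transition,
                 emission_sd = emission_sd, tf_restarts = tf_restarts,
                 max_iter = as.integer(max_iter), tol = tol,
                 detection_floor = detection_floor,
                 init_neutral = init_neutral),
            class = "mixture_hmm_params")
}

hmm_matrices <- function(params) {
  K <- length(params$states)
  trans <- matrix((1 - params$self_transition) / (K - 1), K, K)
  diag(trans) <- params$self_transition
  init <- rep((1 - params$init_neutral) / (K - 1), K)
  init[params$states == 2L] <- params$init_neutral
  list(trans = trans, init = init)
}

# Observations for the HMM: unmasked log2 ratios plus integer chain ids
# (one chain per chromosome, so the state path restarts at boundaries).
hmm_observations <- function(lr, grid) {
  x <- if (inherits(lr, "corrected_lr")) lr$log2_ratio else lr
  chrom <- grid$bins$chrom
  keep <- !is.na(x)
  list(x = x[keep], chain = as.integer(factor(chrom[keep],
                                              levels = unique(chrom))),
       keep = keep)
}

#' Fit the tumor fraction by EM over a copy-number HMM
#'
#' E-step: forward-backward posteriors over hidden per-bin copy states with
#' Gaussian emissions centered on [expected_log_ratio()] of each state at
#' the current tumor fraction. M-step: bounded 1-D maximization of the
#' expected log-likelihood over `tf`, then a closed-form emission-sd update.
#' The chain is restarted from each value in `params$tf_restarts` and the
#' maximum-likelihood restart is returned. The log-likelihood is
#' non-decreasing across iterations within a restart.
#'
#' @param lr A `corrected_lr` (or numeric log2-ratio vector, NA = masked).
#' @param grid The `genome_grid` the profile lives on (chromosome chain
#'   structure).
#' @param params A [mixture_hmm_params()].
#' @param min_bins Minimum unmasked bins (default 100).
#' @return Object of class `tf_fit`: list with `tf`, `detected`,
#'   `log_likelihood`, `n_iter`, `converged`, `emission_sd`,
#'   `restart_table`, `loglik_trace`, `state_posteriors` (unmasked bins x
#'   states), and the `params` used.
#' @export
fit_tumor_fraction <- function(lr, grid, params = mixture_hmm_params(),
                               min_bins = 100) {
  obs <- hmm_observations(lr, grid)
  n <- length(obs$x)
  if (n < min_bins)
    stop("need >= ", min_bins, " unmasked bins, got ", n, call. = FALSE)
  mats <- hmm_matrices(params)
  states <- params$states

  run_restart <- function(tf0) {
    tf <- tf0; sd <- params$emission_sd
    ll_prev <- -Inf; trace <- numeric(0); converged <- FALSE
    gamma <- NULL; iter <- 0L
    for (iter in seq_len(params$max_iter)) {
      le <- vapply(states, function(s)
        stats::dnorm(obs$x, expected_log_ratio(s, tf), sd, log = TRUE),
        numeric(n))
      fb <- hmm_forward_backward(le, mats$trans, mats$init, obs$chain)
      gamma <- fb$gamma
      trace <- c(trace, fb$loglik)
      if (is.finite(ll_prev) && abs(fb$loglik - ll_prev) < params$tol) {
        converged <- TRUE
        break
      }
      ll_prev <- fb$loglik
      # M-step: tf by bounded search at current sd, then closed-form sd
      qfun <- function(t) {
        mu <- expected_log_ratio(states, t)
        sum(vapply(seq_along(states), function(k)
          sum(gamma[, k] * stats::dnorm(obs$x, mu[k], sd, log = TRUE)),
          numeric(1)))
      }
      tf <- stats::optimize(qfun, c(0, 0.999), maximum = TRUE,
                            tol = 1e-5)$maximum
      mu <- expected_log_ratio(states, tf)
      sd <- sqrt(sum(vapply(seq_along(states), function(k)
        sum(gamma[, k] * (obs$x - mu[k])^2), numeric(1))) / n)
      sd <- max(sd, 0.01)
    }
    list(tf0 = tf0, tf = tf, sd = sd, loglik = trace[length(trace)],
         n_iter = iter, converged = converged, trace = trace,
         gamma = gamma)
  }

  fits <- lapply(params$tf_restarts, run_restart)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  restart_table <- data.frame(
    tf_init = vapply(fits, `[[`, numeric(1), "tf0"),
    tf_final = vapply(fits, `[[`, numeric(1), "tf"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_iter = vapply(fits, `[[`, numeric(1), "n_iter"),
    converged = vapply(fits, `[[`, logical(1), "converged"))

  structure(list(tf = best$tf, detected = best$tf >= params$detection_floor,
                 log_likelihood = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, emission_sd = best$sd,
                 restart_table = restart_table,
                 loglik_trace = best$trace,
                 state_posteriors = best$gamma, params = params),
            class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  cat(sprintf(
    "tf_fit: tf = %.4f (%s), loglik = %.2f, sd = %.3f, %s in %d iter\n",
    x$tf, if (x$detected) "detected" else "not detected",
    x$log_likelihood, x$emission_sd,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Most-probable copy-number state path
#'
#' Viterbi decoding of the fitted HMM; masked bins carry no state.
#'
#' @param lr The profile passed to [fit_tumor_fraction()].
#' @param grid The `genome_grid`.
#' @param fit A `tf_fit`.
#' @return `data.frame` with `chrom`, `start`, `end`, `log2_ratio`, `state`
#'   (integer copy number, NA on masked bins) — ready for [write_seg()].
#' @export
viterbi_states <- function(lr, grid, fit) {
  obs <- hmm_observations(lr, grid)
  params <- fit$params
  mats <- hmm_matrices(params)
  le <- vapply(params$states, function(s)
    stats::dnorm(obs$x, expected_log_ratio(s, fit$tf), fit$emission_sd,
                 log = TRUE), numeric(length(obs$x)))
  path <- hmm_viterbi(le, mats$trans, mats$init, obs$chain)
  state <- rep(NA_integer_, n_bins(grid))
  state[obs$keep] <- params$states[path]
  x <- if (inherits(lr, "corrected_lr")) lr$log2_ratio else lr
  data.frame(grid$bins[, c("chrom", "start", "end")],
             log2_ratio = x, state = state, row.names = NULL)
}
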