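#' @useDynLib plasmafrac, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state, so every stochastic function in the
#' package is a pure function of its arguments and its `seed`.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a string, folded into [0, 2^31).  Used to derive
# per-stage seeds and to stamp reports with a config fingerprint without
# pulling in a hashing dependency.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

#' Derive a per-stage seed from a global seed
#'
#' Rule: `(global_seed * 7919 + fnv1a32(stage_name)) mod (2^31 - 1)`, so a
#' single documented integer reproduces every stage of a run while stages
#' remain statistically decoupled.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  as.integer((as.double(global_seed) * 7919 + fnv1a32(stage)) %% (2^31 - 1))
}

# Fingerprint an R object (config lists etc.) by hashing its deparsed form.
config_hash <- function(x) {
  sprintf("%08x", fnv1a32(paste(deparse(x, control = "all"), collapse = "\n")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
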