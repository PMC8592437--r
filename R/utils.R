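# Time conventions: AML dynamics run in days, CML in months; trajectories
# always report time in months.
DAYS_PER_MONTH <- 30.44

months_to_days <- function(m) m * DAYS_PER_MONTH
days_to_months <- function(d) d / DAYS_PER_MONTH

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline (parameter sampling, schedule
#' sampling, noise, sparsification, network training, fold assignment) draws
#' its own seed deterministically from the master seed and a stage label, so
#' a single integer reproduces a full run while stages stay independent.
#' The derivation is `(seed * 48271 + hash(label)) mod (2^31 - 1)` with a
#' plain polynomial string hash.
#'
#' @param seed master seed (integer).
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% (m - 1) + 1)
}

# Evaluate expr under a local RNG state; NULL seed means "use current RNG".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopif_nonfinite <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}
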