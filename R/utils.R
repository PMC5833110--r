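# Internal helpers shared across modules.

# data.table syntax is used inside this package without a full import.
.datatable.aware <- TRUE

#' Clamp probabilities into [0, 1 - eps]
#'
#' A Gamma density can exceed 1 for small scale parameters, but it is used
#' here as a Bernoulli success probability, so rates are clamped just below 1
#' before any probabilistic use.
#'
#' @param p numeric vector.
#' @param eps upper-tail guard; the maximum returned value is `1 - eps`.
#' @return numeric vector in `[0, 1 - eps]`.
#' @keywords internal
#' @noRd
clamp01 <- function(p, eps = 1e-9) {
  pmin(pmax(p, 0), 1 - eps)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed from a parent seed and an offset.
# Kept strictly inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 8191) %% 2147483587
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-boundary logging used by the pipeline so conservation invariants are
# auditable from console output. Quiet by default in scripted use.
fg_log <- function(..., verbose = getOption("fertgp.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[fertgp] ", ...)
  invisible(NULL)
}
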