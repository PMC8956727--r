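clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-item seed from a master seed
#'
#' Counter-based derivation so every patch (or other indexed unit) of a run
#' can be regenerated independently of the rest: the i-th item depends only
#' on `(seed, index)`, never on how many items preceded it.
#'
#' @param seed master seed, a non-negative integer below 2^31.
#' @param index item counter (0, 1, 2, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  i <- as.numeric(index) %% m
  # two rounds of a multiplicative mix (Lehmer-style), kept in doubles:
  # all intermediates < 2^53 because factors < 2^31 and 48271 < 2^16.
  s <- (s * 48271 + i + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s + 1)
}

# Evaluate `expr` with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}
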