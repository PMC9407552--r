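# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic steps in the package funnel through
# this so that no function leaks global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of per-stage seeds from a master seed; keeps values
# inside the 32-bit integer range.
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.double(master) * 1000 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pearscc_error")))
}
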