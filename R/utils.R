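# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Half-up decimal rounding (matching how accuracy tables are printed;
# base round() is half-to-even).
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# argmax over columns of an n x m score matrix, ties -> lowest column index
argmax_rows <- function(scores) max.col(scores, ties.method = "first")

`%||%` <- function(a, b) if (is.null(a)) b else a
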