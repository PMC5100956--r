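# internal helpers

# (1-x)^t without underflow/accumulation for large t
pow1m <- function(x, t) exp(t * log1p(-x))

check_rst <- function(r, s, t) {
  if (any(r < 0 | r > 0.5)) stop("recombination fraction r must be in [0, 0.5]")
  if (any(s < 0 | s >= 1)) stop("selection coefficient s must be in [0, 1)")
  if (any(t < 0)) stop("t must be non-negative")
  invisible(TRUE)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
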