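# internal numerical helpers

# row-wise log(sum(exp(x))) with the usual max shift; rows of -Inf give -Inf
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# round half away from zero (half-up for non-negative scores)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed) || !is.numeric(seed))
    stop_config("a single integer 'seed' is required for stochastic steps")
  as.integer(seed)
}

# run expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
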