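# Seed handling: evaluate an expression under a local RNG state so that
# simulators are pure functions of their seed without clobbering the caller's
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from a master seed. Participant k always gets
# the same child seed regardless of cohort size, so growing a cohort does not
# reshuffle existing participants. Kept below 2^31 - 1.
derive_seeds <- function(master_seed, n, stream = 0L) {
  if (is.null(master_seed)) return(rep(list(NULL), n))
  m <- 2147483629 # prime < 2^31
  s <- (as.numeric(master_seed) %% m)
  vapply(seq_len(n), function(k) {
    ((s * 48271 + stream * 16807 + k * 69621) %% m) + 1
  }, numeric(1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
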