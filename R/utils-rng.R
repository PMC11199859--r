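# Deterministic seed derivation. Mixes an arbitrary number of non-negative
# integers into a single seed in [1, 2^31 - 2] so that per-window / per-epoch
# RNG substreams are reproducible regardless of how a batch is partitioned.
mix_seed <- function(...) {
  parts <- c(...)
  s <- 104729
  m <- 2147483647 # 2^31 - 1, prime
  for (p in parts) {
    s <- (s * 48271 + (as.double(p) %% m) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded substreams do not disturb the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
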