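# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministically mix integers into one seed in [1, 2^31 - 2].
mixSeed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (p %% 2147483647)) %% 2147483629
  as.integer(h %% 2147483646) + 1L
}
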