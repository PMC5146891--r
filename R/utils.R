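# Internal helpers shared across modules.

# Deterministic sub-seed derivation. Keeps every derived seed a valid
# 32-bit integer so the same master seed regenerates every stream.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offsets) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate an expression under a local RNG state so callers' streams
# are never disturbed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
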