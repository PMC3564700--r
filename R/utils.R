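# Internal helpers: deterministic hierarchical seeding and scoped RNG use.

# Mix a master seed with integer tags into a 31-bit substream seed.
# Deterministic, order-sensitive, and independent of the global RNG state.
# All arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 69069 + as.double(t) + 1) %% 2147483647
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
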