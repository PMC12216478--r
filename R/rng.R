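# Seed plumbing. All stochastic entry points take an integer seed and scope
# it with withr::with_seed so the caller's RNG state is never disturbed.
# Sub-seeds are derived arithmetically and kept below 2^31 - 1.

#' Derive a reproducible child seed from a parent seed
#'
#' Deterministic arithmetic derivation used to hand independent seed streams
#' to pipeline stages (cipher keys, backbone init, training, splits) from a
#' single global seed.
#'
#' @param seed integer parent seed.
#' @param offset nonnegative integer stream offset.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derivedSeed(1, 0)
#' derivedSeed(1, 3)
derivedSeed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m) + 1
  v <- (s * 48271 + as.numeric(offset) * 7919 + 1) %% m
  as.integer(v + 1)
}

# Run expr under a seed when one is given; otherwise use the current RNG
# stream (callers inside an outer with_seed stay deterministic either way).
withSeedIf <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
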