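#' KeySet: the four per-block key streams of the block-scrambling cipher
#'
#' A `KeySet` holds the master seed and the four derived streams, one entry
#' per block: `k1` a permutation of block indices (block scrambling), `k2`
#' a dihedral-transform index in 0..7 (rotation / flip), `k3` a binary flag
#' driving the negative-positive pixel inversion, and `k4` a colour-channel
#' permutation index in 1..6. The same `k1`..`k3` streams act on all colour
#' components; `k4` permutes whole channels within a block.
#'
#' @slot masterSeed integer seed the streams were derived from (NA for
#'   hand-built key sets).
#' @slot k1 integer permutation of `1..nBlocks`.
#' @slot k2 integer vector, dihedral indices in `0..7`.
#' @slot k3 integer vector of 0/1 inversion flags.
#' @slot k4 integer vector of channel-permutation indices in `1..6`.
#' @aliases KeySet
#' @exportClass KeySet
setClass("KeySet", representation(
  masterSeed = "integer",
  k1 = "integer",
  k2 = "integer",
  k3 = "integer",
  k4 = "integer"
))

setValidity("KeySet", function(object) {
  n <- length(object@k1)
  msgs <- character()
  if (length(object@k2) != n || length(object@k3) != n ||
      length(object@k4) != n)
    msgs <- c(msgs, "key streams must all have length nBlocks")
  if (!identical(sort(object@k1), seq_len(n)))
    msgs <- c(msgs, "k1 must be a permutation of 1..nBlocks")
  if (n > 0 && (any(object@k2 < 0L) || any(object@k2 > 7L)))
    msgs <- c(msgs, "k2 entries must lie in 0..7")
  if (n > 0 && !all(object@k3 %in% c(0L, 1L)))
    msgs <- c(msgs, "k3 entries must be 0 or 1")
  if (n > 0 && (any(object@k4 < 1L) || any(object@k4 > 6L)))
    msgs <- c(msgs, "k4 entries must lie in 1..6")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn KeySet number of blocks the key set covers
#' @param object,x a `KeySet`.
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname KeySet
#' @export
setMethod("nBlocks", "KeySet", function(x) length(x@k1))

setMethod("show", "KeySet", function(object) {
  cat("KeySet for", nBlocks(object), "blocks",
      if (!is.na(object@masterSeed))
        paste0("(master seed ", object@masterSeed, ")") else "(hand-built)",
      "\n")
  cat("  inversion rate:", signif(mean(object@k3), 3), "\n")
})

#' Derive the four cipher key streams from a master seed
#'
#' The generator contract (part of the cipher's file-format contract): the
#' streams are drawn from R's Mersenne-Twister generator seeded with
#' `masterSeed`, in the fixed order K1 (uniform random permutation via
#' `sample.int`), K2 (iid uniform on 0..7), K3 (iid Bernoulli(0.5)), K4
#' (iid uniform on 1..6). Identical inputs always give identical streams,
#' and the inversion flags have probability 0.5 each, so on average half
#' the blocks are negative-positive inverted.
#'
#' @param masterSeed integer master seed.
#' @param nBlocks number of blocks (>= 1).
#' @return a [KeySet-class] object.
#' @export
#' @examples
#' keys <- deriveKeys(42, 16)
#' nBlocks(keys)
deriveKeys <- function(masterSeed, nBlocks) {
  if (!is.numeric(nBlocks) || length(nBlocks) != 1L || is.na(nBlocks) ||
      nBlocks < 1)
    stop("nBlocks must be a positive integer")
  nBlocks <- as.integer(nBlocks)
  masterSeed <- as.integer(masterSeed)
  withr::with_seed(masterSeed, {
    k1 <- sample.int(nBlocks)
    k2 <- sample(0:7, nBlocks, replace = TRUE)
    k3 <- sample(0:1, nBlocks, replace = TRUE)
    k4 <- sample.int(6L, nBlocks, replace = TRUE)
  })
  new("KeySet", masterSeed = masterSeed, k1 = as.integer(k1),
      k2 = as.integer(k2), k3 = as.integer(k3), k4 = as.integer(k4))
}

#' Identity key set (cipher becomes a no-op)
#'
#' Useful for testing individual scrambling steps in isolation: `k1` is the
#' identity permutation, `k2 = 0` (identity dihedral transform), `k3 = 0`
#' (no inversion), `k4 = 1` (identity channel permutation).
#'
#' @param nBlocks number of blocks.
#' @return a [KeySet-class] object.
#' @export
identityKeys <- function(nBlocks) {
  nBlocks <- as.integer(nBlocks)
  new("KeySet", masterSeed = NA_integer_, k1 = seq_len(nBlocks),
      k2 = integer(nBlocks), k3 = integer(nBlocks),
      k4 = rep(1L, nBlocks))
}
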