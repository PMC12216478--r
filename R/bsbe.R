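# The block-scrambling cipher: four per-block steps under the K1..K4 key
# streams. Encryption order (fixed contract):
#   1. scramble block positions by K1,
#   2. dihedral transform (rotate/flip) each block by K2,
#   3. negative-positive pixel inversion where K3 = 1,
#   4. colour-channel permutation by K4.
# Decryption applies the exact inverses in reverse order; the inversion
# step is its own inverse.

# fixed enumeration of the six permutations of (R, G, B); index 1 = identity
PERM3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Negative-positive pixel inversion
#'
#' When the key bit is 1, every pixel `p` becomes `p XOR (2^L - 1)`, i.e.
#' the bitwise complement within the bit depth, computed as
#' `(2^L - 1) - p` (the two are identical for `p < 2^L`). When the bit is
#' 0 the block passes through unchanged. The same flag applies to all
#' colour components of the block. The transform is an involution.
#'
#' @param block pixel block (any integer array).
#' @param r key bit, 0 or 1.
#' @param bitDepth bits per channel (default 8).
#' @return transformed block, same shape and storage mode.
#' @export
#' @examples
#' negposTransform(array(0L, c(2, 2, 1)), 1)[1]    # 255
#' negposTransform(array(100L, c(1, 1, 1)), 1)[1]  # 155
negposTransform <- function(block, r, bitDepth = 8L) {
  stopifnot(r %in% c(0, 1))
  mx <- as.integer(2^bitDepth - 1)
  if (any(block > mx) || any(block < 0))
    stop("pixel values exceed the stated bit depth")
  if (r == 0) return(block)
  out <- mx - block
  storage.mode(out) <- storage.mode(block)
  out
}

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Dihedral transform of a square block
#'
#' Applies one of the 8 symmetries of the square, indexed 0..7:
#' `k %% 4` counter-clockwise quarter-turns, preceded by a horizontal flip
#' (column reversal) when `k >= 4`. Index 0 is the identity. The pixel
#' multiset is preserved; [dihedralInverse()] gives the index that undoes
#' each transform.
#'
#' @param block square pixel block (`n x n x C` or `n x n`).
#' @param k transform index in 0..7.
#' @return transformed block.
#' @export
#' @examples
#' b <- array(1:9, c(3, 3, 1))
#' identical(dihedralTransform(b, 0), b)
dihedralTransform <- function(block, k) {
  stopifnot(k %in% 0:7)
  d2 <- length(dim(block)) == 2L
  if (d2) dim(block) <- c(dim(block), 1L)
  if (dim(block)[1] != dim(block)[2])
    stop("dihedral transform requires a square block, got ",
         dim(block)[1], " x ", dim(block)[2])
  f <- k %/% 4L; r <- k %% 4L
  out <- block
  for (ch in seq_len(dim(block)[3])) {
    m <- block[, , ch]
    if (f == 1L) m <- m[, ncol(m):1, drop = FALSE]
    if (r > 0L) for (i in seq_len(r)) m <- rot90ccw(m)
    out[, , ch] <- m
  }
  if (d2) dim(out) <- dim(out)[1:2]
  out
}

# inverse-index table computed once by brute force on a marker block
.dihedralInv <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      marker <- matrix(1:9, 3, 3)
      inv <- integer(8)
      for (k in 0:7) {
        tk <- dihedralTransform(marker, k)
        for (j in 0:7) {
          if (identical(dihedralTransform(tk, j), marker)) {
            inv[k + 1L] <- j
            break
          }
        }
      }
      tab <<- inv
    }
    tab
  }
})

#' Inverse index of a dihedral transform
#'
#' @param k transform index in 0..7.
#' @return the index `j` such that applying `j` after `k` restores the
#'   block.
#' @export
dihedralInverse <- function(k) {
  stopifnot(all(k %in% 0:7))
  .dihedralInv()[k + 1L]
}

#' Permute the colour channels of a block
#'
#' Applies the `k`-th permutation of (R, G, B) in the package's fixed
#' enumeration (1 = identity, .., 6; lexicographic order of permutations).
#' Output channel `i` is input channel `perm[i]`.
#'
#' @param block `n x m x 3` pixel block.
#' @param k permutation index in 1..6.
#' @return block with permuted channels.
#' @export
shuffleChannels <- function(block, k) {
  stopifnot(k %in% 1:6)
  if (length(dim(block)) != 3L || dim(block)[3] != 3L)
    stop("channel shuffling requires a 3-channel block")
  block[, , PERM3[k, ], drop = FALSE]
}

#' Index of the inverse channel permutation
#'
#' @param k permutation index in 1..6.
#' @return index of the permutation undoing `k`.
#' @export
shuffleChannelsInverse <- function(k) {
  stopifnot(k %in% 1:6)
  inv <- order(PERM3[k, ])
  which(apply(PERM3, 1, identical, as.integer(inv)))
}

#' Encrypt an image with the block-scrambling cipher
#'
#' Partitions the image into square `blockSize` blocks and applies, in
#' order: block scrambling (K1), per-block dihedral rotation/flip (K2),
#' negative-positive inversion (K3) and colour-channel shuffling (K4, RGB
#' images only). Output has identical shape (after any padding), channel
#' count and bit depth. A key set with too few/many blocks is an error.
#'
#' @param img raster array (H x W x C integers in `[0, 2^L - 1]`).
#' @param keys a [KeySet-class] sized for the partition, or an integer
#'   master seed from which keys are derived.
#' @param blockSize square block edge in pixels (default 16).
#' @param pad reflect-pad non-divisible dimensions (default FALSE = error).
#' @param bitDepth bits per channel (default 8).
#' @return encrypted raster array with attribute `origDim = c(H, W)` when
#'   padding was applied.
#' @seealso [decryptImage()]
#' @export
#' @examples
#' img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
#' enc <- encryptImage(img, keys = 7, blockSize = 16)
#' dec <- decryptImage(enc, keys = 7, blockSize = 16)
#' identical(dec, img)
encryptImage <- function(img, keys, blockSize = 16L, pad = FALSE,
                         bitDepth = 8L) {
  checkRaster(img, bitDepth)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  p <- partitionImage(img, blockSize, pad = pad)
  n <- nBlocks(p$partition)
  if (!is(keys, "KeySet")) keys <- deriveKeys(keys, n)
  if (nBlocks(keys) != n)
    stop("key set covers ", nBlocks(keys), " blocks but the partition has ",
         n)
  rgb <- dim(img)[3] == 3L
  blocks <- p$blocks[keys@k1]                       # step 1: scramble
  for (i in seq_len(n)) {
    b <- dihedralTransform(blocks[[i]], keys@k2[i]) # step 2: rotate/flip
    b <- negposTransform(b, keys@k3[i], bitDepth)   # step 3: inversion
    if (rgb) b <- shuffleChannels(b, keys@k4[i])    # step 4: channels
    blocks[[i]] <- b
  }
  out <- reassembleImage(blocks, p$partition, crop = FALSE)
  if (p$partition@padded)
    attr(out, "origDim") <- c(p$partition@origHeight, p$partition@origWidth)
  out
}

#' Decrypt a block-scrambled image
#'
#' Exact inverse of [encryptImage()]: inverse channel permutation, the
#' (self-inverse) negative-positive inversion, inverse dihedral transform,
#' then the inverse block permutation, and finally cropping back to
#' `origDim` if the plaintext had been padded. Round trips are bit-exact.
#'
#' @inheritParams encryptImage
#' @param origDim optional `c(H, W)` of the original unpadded image; taken
#'   from the ciphertext's `origDim` attribute when present.
#' @return decrypted raster array.
#' @export
decryptImage <- function(img, keys, blockSize = 16L, origDim = NULL,
                         bitDepth = 8L) {
  checkRaster(img, bitDepth)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (is.null(origDim)) origDim <- attr(img, "origDim")
  p <- partitionImage(img, blockSize, pad = FALSE)
  n <- nBlocks(p$partition)
  if (!is(keys, "KeySet")) keys <- deriveKeys(keys, n)
  if (nBlocks(keys) != n)
    stop("key set covers ", nBlocks(keys), " blocks but the partition has ",
         n)
  rgb <- dim(img)[3] == 3L
  blocks <- p$blocks
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    if (rgb) b <- shuffleChannels(b, shuffleChannelsInverse(keys@k4[i]))
    b <- negposTransform(b, keys@k3[i], bitDepth)
    b <- dihedralTransform(b, dihedralInverse(keys@k2[i]))
    blocks[[i]] <- b
  }
  unscrambled <- blocks
  unscrambled[keys@k1] <- blocks                    # undo step 1
  out <- reassembleImage(unscrambled, p$partition, crop = FALSE)
  if (!is.null(origDim))
    out <- out[seq_len(origDim[1]), seq_len(origDim[2]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
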