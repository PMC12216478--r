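#' BlockPartition: how an image divides into cipher blocks
#'
#' Records the block geometry of an image: block size, grid shape, padded
#' dimensions and the original (pre-padding) dimensions so decryption can
#' crop back. Blocks are indexed row-major: block `m` covers grid row
#' `(m-1) %/% nby + 1`, grid column `(m-1) %% nby + 1`.
#'
#' @slot bx,by block height and width in pixels.
#' @slot nbx,nby number of block rows / columns.
#' @slot height,width image dimensions after any padding.
#' @slot origHeight,origWidth dimensions before padding.
#' @slot padded logical, whether reflect-padding was applied.
#' @aliases BlockPartition
#' @exportClass BlockPartition
setClass("BlockPartition", representation(
  bx = "integer", by = "integer",
  nbx = "integer", nby = "integer",
  height = "integer", width = "integer",
  origHeight = "integer", origWidth = "integer",
  padded = "logical"
))

setValidity("BlockPartition", function(object) {
  if (object@nbx * object@bx != object@height ||
      object@nby * object@by != object@width)
    "block grid does not tile the (padded) image" else TRUE
})

setMethod("show", "BlockPartition", function(object) {
  cat(sprintf("BlockPartition: %d x %d image, %d x %d blocks (%d total)%s\n",
              object@height, object@width, object@bx, object@by,
              object@nbx * object@nby,
              if (object@padded) " [reflect-padded]" else ""))
})

#' @describeIn BlockPartition total number of blocks
#' @param x a `BlockPartition`.
#' @export
setMethod("nBlocks", "BlockPartition", function(x) x@nbx * x@nby)

# reflect-pad an image on the bottom/right so dimensions divide the block
reflectPad <- function(img, bottom, right) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (bottom > 0) {
    ridx <- H - seq_len(bottom) + 1L   # mirror the last rows
    img <- img[c(seq_len(H), ridx), , , drop = FALSE]
  }
  if (right > 0) {
    cidx <- W - seq_len(right) + 1L
    img <- img[, c(seq_len(W), cidx), , drop = FALSE]
  }
  img
}

#' Partition an image into non-overlapping blocks
#'
#' Divides an `X x Y` image into `bx x by` pixel blocks in row-major order.
#' If the dimensions are not divisible, the default is an error naming the
#' offending axis; with `pad = TRUE` the image is reflect-padded on the
#' bottom/right and the original dimensions are recorded in the partition
#' so the inverse can crop back.
#'
#' @param img raster array (H x W x C or H x W).
#' @param bx block height in pixels.
#' @param by block width in pixels (default `bx`).
#' @param pad logical; reflect-pad non-divisible images instead of erroring.
#' @return list with `blocks` (list of `bx x by x C` arrays, row-major
#'   block order) and `partition` (a [BlockPartition-class]).
#' @export
#' @examples
#' img <- array(0L, c(32, 32, 3))
#' p <- partitionImage(img, 16)
#' length(p$blocks)  # 4
partitionImage <- function(img, bx, by = bx, pad = FALSE) {
  checkRaster(img)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  bx <- as.integer(bx); by <- as.integer(by)
  stopifnot(bx >= 1L, by >= 1L)
  H <- dim(img)[1]; W <- dim(img)[2]
  rh <- H %% bx; rw <- W %% by
  if ((rh != 0L || rw != 0L) && !pad) {
    ax <- c(if (rh != 0L) sprintf("height %d %% block height %d", H, bx),
            if (rw != 0L) sprintf("width %d %% block width %d", W, by))
    stop("image dimensions not divisible by block size (",
         paste(ax, collapse = "; "), "); use pad = TRUE to reflect-pad")
  }
  padded <- (rh != 0L || rw != 0L)
  if (padded)
    img <- reflectPad(img, if (rh) bx - rh else 0L, if (rw) by - rw else 0L)
  Hp <- dim(img)[1]; Wp <- dim(img)[2]
  nbx <- Hp %/% bx; nby <- Wp %/% by
  blocks <- vector("list", nbx * nby)
  for (bi in seq_len(nbx)) {
    rows <- (bi - 1L) * bx + seq_len(bx)
    for (bj in seq_len(nby)) {
      cols <- (bj - 1L) * by + seq_len(by)
      blocks[[(bi - 1L) * nby + bj]] <- img[rows, cols, , drop = FALSE]
    }
  }
  part <- new("BlockPartition", bx = bx, by = by, nbx = nbx, nby = nby,
              height = Hp, width = Wp, origHeight = H, origWidth = W,
              padded = padded)
  list(blocks = blocks, partition = part)
}

#' Reassemble blocks into an image
#'
#' Inverse of [partitionImage()]: places blocks back in row-major order and
#' (by default) crops away any reflect padding.
#'
#' @param blocks list of blocks in row-major order.
#' @param partition the [BlockPartition-class] from [partitionImage()].
#' @param crop drop padded rows/columns (default TRUE).
#' @return raster array.
#' @export
reassembleImage <- function(blocks, partition, crop = TRUE) {
  stopifnot(length(blocks) == nBlocks(partition))
  C <- dim(blocks[[1]])[3]
  img <- array(0L, c(partition@height, partition@width, C))
  bx <- partition@bx; by <- partition@by; nby <- partition@nby
  for (m in seq_along(blocks)) {
    bi <- (m - 1L) %/% nby + 1L
    bj <- (m - 1L) %% nby + 1L
    img[(bi - 1L) * bx + seq_len(bx),
        (bj - 1L) * by + seq_len(by), ] <- blocks[[m]]
  }
  if (crop && partition@padded)
    img <- img[seq_len(partition@origHeight),
               seq_len(partition@origWidth), , drop = FALSE]
  storage.mode(img) <- "integer"
  img
}
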