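# Raster images are plain H x W x C arrays of integers in [0, 2^L - 1],
# height first (row-major viewing), C in {1, 3}. L defaults to 8.

#' Validate a raster image array
#'
#' @param img array to check.
#' @param bitDepth bits per channel (default 8).
#' @return the image, invisibly, after validation.
#' @export
checkRaster <- function(img, bitDepth = 8L) {
  if (!is.array(img) || !(length(dim(img)) %in% c(2L, 3L)))
    stop("image must be an H x W or H x W x C array")
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (!dim(img)[3] %in% c(1L, 3L))
    stop("channel count must be 1 or 3, got ", dim(img)[3])
  mx <- 2^bitDepth - 1
  if (any(img < 0) || any(img > mx))
    stop("pixel values must lie in [0, ", mx, "]")
  invisible(img)
}

#' Read an 8-bit PNG or JPEG-free image file as an integer raster array
#'
#' Reads a PNG into an H x W x C integer array in `[0, 255]`. An alpha
#' channel, if present, is dropped.
#'
#' @param path file path to a PNG image.
#' @return integer array H x W x C.
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L) a <- a[, , 1L, drop = FALSE]
  storage.mode(a) <- "double"
  r <- round(a * 255)
  storage.mode(r) <- "integer"
  r
}

#' Write an integer raster array to a lossless PNG file
#'
#' PNG is lossless, so ciphertext written with this function decrypts
#' bit-exactly after re-reading.
#'
#' @param img integer array H x W x C with values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  checkRaster(img)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  a <- img / 255
  if (dim(a)[3] == 1L) a <- a[, , 1L]
  png::writePNG(a, target = path)
  invisible(path)
}

# Bilinear resize to size x size, returning a double array in [0, 1].
# Accepts integer [0, 255] or double [0, 1] input.
resizeNormalize <- function(img, size) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  x <- img
  storage.mode(x) <- "double"
  if (max(x) > 1) x <- x / 255
  if (dim(x)[1] != size || dim(x)[2] != size) {
    x <- EBImage::resize(x, w = size, h = size)
    x <- pmin(pmax(x, 0), 1)
  }
  x
}
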