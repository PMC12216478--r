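# Reduced-scale convolutional feature extractors in three architecture
# styles, built on a plain im2col + matrix-multiply convolution engine.
# Extractors are deterministic functions of (spec, seed): weights are
# He-initialized from the seed and then fixed, so extraction is a pure
# function of (parameters, image). Features are the global-average-pooled
# activations of the last convolutional stage.

# ---- convolution primitives -------------------------------------------

heInit <- function(dims, fanIn) {
  array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
}

# 'same'-padded 2-D convolution via im2col; x: H x W x Cin,
# w: kh x kw x Cin x Cout
conv2d <- function(x, w, b, stride = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  H <- dim(x)[1]; W <- dim(x)[2]
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  xp <- array(0, c(Hp, Wp, cin))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  oi <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  oj <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  cols <- matrix(0, Ho * Wo, kh * kw * cin)
  m <- 1L
  for (ch in seq_len(cin)) {
    chOff <- (ch - 1L) * Hp * Wp
    for (dj in 0:(kw - 1L)) {
      colOff <- chOff + (oj + dj - 1L) * Hp
      for (di in 0:(kh - 1L)) {
        cols[, m] <- xp[oi + di + colOff]
        m <- m + 1L
      }
    }
  }
  out <- cols %*% matrix(w, kh * kw * cin, cout)
  out <- sweep(out, 2, b, "+")
  array(out, c(Ho, Wo, cout))
}

# depthwise 3x3 convolution; w: kh x kw x C
dwconv2d <- function(x, w, b, stride = 1L) {
  C <- dim(x)[3]
  res <- vector("list", C)
  for (ch in seq_len(C)) {
    wk <- array(w[, , ch], c(dim(w)[1], dim(w)[2], 1L, 1L))
    res[[ch]] <- conv2d(x[, , ch, drop = FALSE], wk, b[ch], stride)
  }
  array(unlist(res), c(dim(res[[1]])[1:2], C))
}

relu <- function(x) x * (x > 0)

maxPool2 <- function(x) {
  Ho <- dim(x)[1] %/% 2L; Wo <- dim(x)[2] %/% 2L
  x <- x[seq_len(2L * Ho), seq_len(2L * Wo), , drop = FALSE]
  o <- seq(1L, 2L * Ho, 2L); p <- seq(1L, 2L * Wo, 2L)
  pmax(x[o, p, , drop = FALSE], x[o + 1L, p, , drop = FALSE],
       x[o, p + 1L, , drop = FALSE], x[o + 1L, p + 1L, , drop = FALSE])
}

# 3x3 same average pooling (inception pooling branch)
avgPool3same <- function(x) {
  C <- dim(x)[3]
  w <- array(0, c(3, 3, C))
  w[] <- 1 / 9
  dwconv2d(x, w, rep(0, C), 1L)
}

globalAvgPool <- function(x) apply(x, 3, mean)

# ---- layer constructors and forward pass ------------------------------

mkConv <- function(kh, kw, cin, cout, stride = 1L, act = TRUE) {
  list(type = "conv", w = heInit(c(kh, kw, cin, cout), kh * kw * cin),
       b = rep(0, cout), stride = stride, act = act, cout = cout)
}

mkDwConv <- function(k, C, stride = 1L) {
  list(type = "dwconv", w = heInit(c(k, k, C), k * k),
       b = rep(0, C), stride = stride)
}

# MobileNet-style inverted residual: 1x1 expand -> depthwise 3x3 ->
# 1x1 linear project, with identity shortcut when stride 1 and matching
# channel counts.
mkInvertedResidual <- function(cin, cout, expand = 2L, stride = 1L) {
  mid <- cin * expand
  list(type = "invres",
       expand = mkConv(1L, 1L, cin, mid),
       dw = mkDwConv(3L, mid, stride),
       project = mkConv(1L, 1L, mid, cout, act = FALSE),
       shortcut = (stride == 1L && cin == cout))
}

# Inception-style block: parallel 1x1 / 3x3 / 5x5 (with 1x1 reductions)
# and an average-pool projection branch, concatenated along channels.
mkInception <- function(cin, c1, c3r, c3, c5r, c5, cp) {
  list(type = "incep",
       b1 = list(mkConv(1L, 1L, cin, c1)),
       b3 = list(mkConv(1L, 1L, cin, c3r), mkConv(3L, 3L, c3r, c3)),
       b5 = list(mkConv(1L, 1L, cin, c5r), mkConv(5L, 5L, c5r, c5)),
       bp = list(mkConv(1L, 1L, cin, cp)),
       cout = c1 + c3 + c5 + cp)
}

forwardLayer <- function(layer, x, shortcut = TRUE) {
  switch(layer$type,
    conv = {
      o <- conv2d(x, layer$w, layer$b, layer$stride)
      if (layer$act) relu(o) else o
    },
    dwconv = relu(dwconv2d(x, layer$w, layer$b, layer$stride)),
    pool = maxPool2(x),
    invres = {
      o <- forwardLayer(layer$expand, x)
      o <- forwardLayer(layer$dw, o)
      o <- forwardLayer(layer$project, o)
      if (shortcut && layer$shortcut) o + x else o
    },
    incep = {
      o1 <- x
      for (l in layer$b1) o1 <- forwardLayer(l, o1)
      o3 <- x
      for (l in layer$b3) o3 <- forwardLayer(l, o3)
      o5 <- x
      for (l in layer$b5) o5 <- forwardLayer(l, o5)
      op <- avgPool3same(x)
      for (l in layer$bp) op <- forwardLayer(l, op)
      array(c(o1, o3, o5, op),
            c(dim(o1)[1], dim(o1)[2],
              dim(o1)[3] + dim(o3)[3] + dim(o5)[3] + dim(op)[3]))
    },
    stop("unknown layer type ", layer$type))
}

# ---- the extractor class ----------------------------------------------

#' BackboneExtractor: a fixed convolutional feature extractor
#'
#' Holds the layer stack and weights of one reduced-scale backbone.
#' Construction is deterministic given `(family, inputSize, width, seed)`.
#'
#' @slot family one of `"mobilenet"`, `"inception"`, `"alexnet"`.
#' @slot inputSize square input edge in pixels.
#' @slot width integer width multiplier.
#' @slot layers the layer list.
#' @slot outputDim feature vector length.
#' @slot seed the initialization seed.
#' @aliases BackboneExtractor
#' @exportClass BackboneExtractor
setClass("BackboneExtractor", representation(
  family = "character", inputSize = "integer", width = "numeric",
  layers = "list", outputDim = "integer", seed = "integer"
))

setMethod("show", "BackboneExtractor", function(object) {
  cat(sprintf("BackboneExtractor: %s style, input %dx%d, %d features\n",
              object@family, object@inputSize, object@inputSize,
              object@outputDim))
})

#' Build a reduced-scale convolutional backbone
#'
#' Three architecture families are available, each ending in global
#' average pooling of the last convolutional stage:
#' \describe{
#'   \item{mobilenet}{3x3 stem then inverted residual blocks
#'     (1x1 expansion, depthwise 3x3, linear 1x1 projection) with identity
#'     shortcuts at stride 1 / equal channels; 1x1 head. ReLU throughout.}
#'   \item{inception}{3x3 stem then two inception blocks whose 1x1 / 3x3 /
#'     5x5 and pooling branches are concatenated along channels, with
#'     max-pooling between stages.}
#'   \item{alexnet}{a wide 7x7 first receptive field capturing low-level
#'     structure, then progressively smaller 5x5 / 3x3 kernels with
#'     max-pooling (the canonical large-first-kernel design).}
#' }
#' Weights are He-initialized from `seed` and fixed: the extractor is used
#' as a random-feature map whose output feeds the trained classifier.
#'
#' @param family `"mobilenet"`, `"inception"` or `"alexnet"`.
#' @param inputSize input image edge in pixels (default 64).
#' @param width positive integer width multiplier (default 1).
#' @param seed initialization seed.
#' @return a [BackboneExtractor-class].
#' @export
#' @examples
#' bb <- buildBackbone("alexnet", seed = 1)
#' bb@outputDim
buildBackbone <- function(family = c("mobilenet", "inception", "alexnet"),
                          inputSize = 64L, width = 1, seed = 1L) {
  family <- match.arg(family)
  stopifnot(width >= 1, inputSize >= 16)
  w <- as.integer(width)
  layers <- withr::with_seed(as.integer(seed), switch(family,
    mobilenet = list(
      mkConv(3L, 3L, 3L, 8L * w, stride = 2L),
      mkInvertedResidual(8L * w, 16L * w, expand = 2L, stride = 2L),
      mkInvertedResidual(16L * w, 16L * w, expand = 2L, stride = 1L),
      mkInvertedResidual(16L * w, 24L * w, expand = 2L, stride = 2L),
      mkInvertedResidual(24L * w, 24L * w, expand = 2L, stride = 1L),
      mkConv(1L, 1L, 24L * w, 32L * w)
    ),
    inception = list(
      mkConv(3L, 3L, 3L, 8L * w, stride = 2L),
      list(type = "pool"),
      mkInception(8L * w, 8L * w, 4L * w, 8L * w, 2L * w, 4L * w, 4L * w),
      list(type = "pool"),
      mkInception(24L * w, 8L * w, 4L * w, 12L * w, 2L * w, 8L * w, 4L * w)
    ),
    alexnet = list(
      mkConv(7L, 7L, 3L, 12L * w, stride = 2L),
      list(type = "pool"),
      mkConv(5L, 5L, 12L * w, 16L * w),
      list(type = "pool"),
      mkConv(3L, 3L, 16L * w, 24L * w),
      mkConv(3L, 3L, 24L * w, 24L * w),
      list(type = "pool")
    )))
  outDim <- switch(family, mobilenet = 32L * w, inception = 32L * w,
                   alexnet = 24L * w)
  new("BackboneExtractor", family = family,
      inputSize = as.integer(inputSize), width = width, layers = layers,
      outputDim = outDim, seed = as.integer(seed))
}

#' Extract a feature vector from one image
#'
#' The image is bilinearly resized to the extractor's input size, scaled
#' to `[0, 1]` channel-wise, pushed through the layer stack and globally
#' average-pooled. Deterministic: identical images give identical vectors.
#'
#' @param backbone a [BackboneExtractor-class].
#' @param img raster array (integer `[0, 255]` or double `[0, 1]`).
#' @return numeric feature vector of length `backbone@outputDim`, with a
#'   `source` attribute naming the family.
#' @export
extractFeatures <- function(backbone, img) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 1L) img <- array(rep(img, 3), c(dim(img)[1:2], 3L))
  x <- resizeNormalize(img, backbone@inputSize)
  for (layer in backbone@layers) x <- forwardLayer(layer, x)
  v <- globalAvgPool(x)
  if (!all(is.finite(v))) stop("non-finite features extracted")
  structure(v, source = backbone@family)
}

#' Extract a feature matrix from a list of images
#'
#' @param backbone a [BackboneExtractor-class].
#' @param imgs list of raster arrays, or a [LesionDataset-class].
#' @return numeric matrix, one row per image.
#' @export
extractFeatureMatrix <- function(backbone, imgs) {
  if (is(imgs, "LesionDataset")) imgs <- images(imgs)
  t(vapply(imgs, function(im) as.numeric(extractFeatures(backbone, im)),
           numeric(backbone@outputDim)))
}
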