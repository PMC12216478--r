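# Download-free generator of labelled, dermoscopy-like synthetic images.
# Each class is a parametric appearance family: an elliptical lesion blob
# on a skin-tone background with class-dependent hue, eccentricity, border
# irregularity and texture noise. A separability knob in [0, 1] scales the
# between-class parameter distance; at 0 all classes share one appearance.

# Default per-class counts mirror a 9-class dermoscopy archive's imbalance
# (2239 images total), scalable by a factor.
ISIC_CLASS_COUNTS <- c(114L, 376L, 95L, 438L, 357L, 462L, 77L, 181L, 139L)

#' LesionDataset: labelled synthetic lesion images
#'
#' Container for a list of raster images with integer class labels `1..K`
#' and the generating specification.
#'
#' @slot images list of H x W x 3 integer arrays in `[0, 255]`.
#' @slot labels integer class labels, one per image.
#' @slot K number of classes.
#' @slot spec the generating specification (list).
#' @aliases LesionDataset
#' @exportClass LesionDataset
setClass("LesionDataset", representation(
  images = "list", labels = "integer", K = "integer", spec = "list"
))

setValidity("LesionDataset", function(object) {
  if (length(object@images) != length(object@labels))
    return("images and labels differ in length")
  if (length(object@labels) && (any(object@labels < 1L) ||
                                any(object@labels > object@K)))
    return("labels out of range 1..K")
  TRUE
})

setMethod("show", "LesionDataset", function(object) {
  cat("LesionDataset:", length(object@images), "images,", object@K,
      "classes\n")
  if (length(object@labels))
    cat("  per class:", paste(tabulate(object@labels, object@K),
                              collapse = " "), "\n")
})

#' @describeIn LesionDataset number of images
#' @param x a `LesionDataset`.
#' @export
setMethod("length", "LesionDataset", function(x) length(x@images))

#' @describeIn LesionDataset integer class labels
#' @export
setGeneric("labels")

#' @rdname LesionDataset
#' @param object a `LesionDataset`.
#' @param ... unused.
#' @export
setMethod("labels", "LesionDataset", function(object, ...) object@labels)

#' @describeIn LesionDataset list of image arrays
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname LesionDataset
#' @export
setMethod("images", "LesionDataset", function(x) x@images)

#' Specification for a synthetic lesion dataset
#'
#' @param classCounts integer vector of per-class image counts. Default:
#'   the 9-class archive-shaped counts `c(114, 376, 95, 438, 357, 462,
#'   77, 181, 139)` scaled by `scale`.
#' @param scale factor applied to the default counts (default 0.1, i.e.
#'   about 224 images — desk scale).
#' @param imageSize square image edge in pixels (default 64).
#' @param separability class-separation knob in `[0, 1]` (default 0.8).
#' @param seed integer seed.
#' @return list spec for [generateLesionDataset()].
#' @export
lesionDatasetSpec <- function(classCounts = NULL, scale = 0.1,
                              imageSize = 64L, separability = 0.8,
                              seed = 1L) {
  if (is.null(classCounts))
    classCounts <- pmax(2L, as.integer(round(ISIC_CLASS_COUNTS * scale)))
  classCounts <- as.integer(classCounts)
  if (any(classCounts < 1L)) stop("per-class counts must be >= 1")
  if (separability < 0 || separability > 1)
    stop("separability must lie in [0, 1]")
  list(classCounts = classCounts, K = length(classCounts),
       imageSize = as.integer(imageSize), separability = separability,
       seed = as.integer(seed))
}

# deterministic per-class appearance parameters; at separability 0 every
# class collapses onto the shared base appearance
lesionClassParams <- function(K, separability) {
  s <- separability
  base <- c(0.38, 0.24, 0.20)  # shared brownish lesion colour
  lapply(seq_len(K), function(k) {
    hue <- (k - 1) / K
    cc <- as.numeric(col2rgb(hsv(hue, 0.65, 0.45))) / 255
    list(
      color = (1 - s) * base + s * cc,
      ecc = 0.1 + s * 0.75 * (k - 1) / max(1, K - 1),
      borderFreq = 3 + (k - 1) %% 5,
      borderAmp = s * 0.05 * (1 + (k - 1) %/% 3),
      textureSd = 0.02 + s * 0.05 * ((k - 1) %% 4) / 3,
      sizeFrac = 0.24 + s * 0.10 * ((k - 1) %% 3) / 2
    )
  })
}

# render one lesion image (double [0,1] -> integer [0,255])
renderLesion <- function(size, par) {
  skin <- c(0.88, 0.72, 0.62) + rnorm(3, 0, 0.02)
  cx <- size / 2 + runif(1, -0.08, 0.08) * size
  cy <- size / 2 + runif(1, -0.08, 0.08) * size
  r0 <- par$sizeFrac * size * runif(1, 0.85, 1.15)
  theta0 <- runif(1, 0, pi)
  phase <- runif(1, 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), size), size, size)        # row coord
  ys <- matrix(rep(seq_len(size), each = size), size, size) # col coord
  dx <- xs - cx; dy <- ys - cy
  xr <- cos(theta0) * dx + sin(theta0) * dy
  yr <- -sin(theta0) * dx + cos(theta0) * dy
  b <- r0 * (1 - par$ecc * 0.8)
  ang <- atan2(yr, xr)
  wobble <- 1 + par$borderAmp * sin(par$borderFreq * ang + phase)
  d <- sqrt((xr / r0)^2 + (yr / b)^2) / wobble
  mask <- 1 / (1 + exp((d - 1) / 0.06))                     # soft border
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    tex <- matrix(rnorm(size * size, 0, par$textureSd), size, size)
    bgn <- matrix(rnorm(size * size, 0, 0.015), size, size)
    img[, , ch] <- (skin[ch] + bgn) * (1 - mask) +
      (par$color[ch] + tex) * mask
  }
  out <- round(pmin(pmax(img, 0), 1) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Generate a labelled synthetic lesion dataset
#'
#' Renders `sum(classCounts)` images. Each class has a distinct parametric
#' appearance (colour, eccentricity, border irregularity, texture); the
#' spec's `separability` scales how far apart the class appearances sit.
#' Fully reproducible from the spec's seed.
#'
#' @param spec a spec from [lesionDatasetSpec()].
#' @return a [LesionDataset-class].
#' @export
#' @examples
#' ds <- generateLesionDataset(lesionDatasetSpec(classCounts = c(2, 2, 2),
#'                                               imageSize = 32))
#' length(ds)          # 6
#' table(labels(ds))
generateLesionDataset <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$classCounts))
  pars <- lesionClassParams(spec$K, spec$separability)
  withr::with_seed(spec$seed, {
    imgs <- vector("list", sum(spec$classCounts))
    labs <- integer(sum(spec$classCounts))
    m <- 1L
    for (k in seq_len(spec$K)) {
      for (i in seq_len(spec$classCounts[k])) {
        imgs[[m]] <- renderLesion(spec$imageSize, pars[[k]])
        labs[m] <- k
        m <- m + 1L
      }
    }
  })
  new("LesionDataset", images = imgs, labels = labs, K = spec$K,
      spec = spec)
}

#' Stratified train/test split
#'
#' Splits each class independently so class proportions carry over: per
#' class, `round(trainFraction * n_k)` images (at least 1, at most
#' `n_k - 1`) go to training. The two parts are disjoint and exhaustive.
#'
#' @param dataset a [LesionDataset-class].
#' @param trainFraction fraction in (0, 1) (the study splits are 0.8 and
#'   0.7).
#' @param seed integer seed for the within-class shuffles.
#' @return list with `train` and `test` [LesionDataset-class]s and the
#'   index vectors `trainIdx`, `testIdx`.
#' @export
splitDataset <- function(dataset, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  labs <- labels(dataset)
  cnt <- tabulate(labs, dataset@K)
  if (any(cnt < 2L))
    stop("stratified split needs >= 2 images per class; class ",
         which(cnt < 2L)[1], " has ", min(cnt))
  trainIdx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(dataset@K)) {
      idx <- which(labs == k)
      nTr <- min(max(1L, as.integer(round(trainFraction * length(idx)))),
                 length(idx) - 1L)
      trainIdx <- c(trainIdx, sample(idx, nTr))
    }
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(labs), trainIdx)
  sub <- function(ix) new("LesionDataset", images = dataset@images[ix],
                          labels = labs[ix], K = dataset@K,
                          spec = dataset@spec)
  list(train = sub(trainIdx), test = sub(testIdx),
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Write a dataset to disk as PNGs + CSV labels + JSON manifest
#'
#' Emits one lossless PNG per image, a `labels.csv` file with columns
#' `filename,label` and a `manifest.json` recording the generating spec,
#' so fixtures round-trip exactly through [readLesionDirectory()].
#'
#' @param dataset a [LesionDataset-class].
#' @param outdir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
writeFixtures <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  labs <- labels(dataset)
  files <- sprintf("class%d_img%04d.png", labs, seq_along(labs))
  for (i in seq_along(files))
    writeImagePNG(dataset@images[[i]], file.path(outdir, files[i]))
  df <- data.frame(filename = files, label = labs)
  write.csv(df, file.path(outdir, "labels.csv"), row.names = FALSE)
  manifest <- list(n = length(labs), K = dataset@K, spec = dataset@spec,
                   files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Load a lesion image directory (PNGs + labels.csv)
#'
#' @param dir directory written by [writeFixtures()] or any directory of
#'   PNGs with a `labels.csv` (`filename,label`).
#' @return a [LesionDataset-class].
#' @export
readLesionDirectory <- function(dir) {
  labfile <- file.path(dir, "labels.csv")
  if (!file.exists(labfile)) stop("no labels.csv in ", dir)
  df <- read.csv(labfile, stringsAsFactors = FALSE)
  imgs <- lapply(df$filename, function(f) readImagePNG(file.path(dir, f)))
  K <- max(df$label)
  spec <- list()
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!is.null(man$spec)) spec <- man$spec
    if (!is.null(man$K)) K <- man$K
  }
  new("LesionDataset", images = imgs, labels = as.integer(df$label),
      K = as.integer(K), spec = as.list(spec))
}
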