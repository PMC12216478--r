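# End-to-end orchestration: encrypt -> decrypt (verified bit-exact) ->
# extract and fuse features -> train the conditional VAE -> evaluate on
# the 80:20 and 70:30 splits, with optional metaheuristic hyperparameter
# tuning. Analysis always runs on the decrypted images; the cipher stage
# exists to certify that privacy-preserving storage/transport does not
# perturb a single pixel of what the classifier sees.

#' Assemble a pipeline configuration
#'
#' Defaults follow the study settings: block size 16 for the cipher;
#' learning rate 0.01, 50 epochs, dropout 0.5, batch size 5 for the
#' classifier; 80:20 and 70:30 train/test splits.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param blockSize cipher block edge in pixels.
#' @param imageSize backbone input edge in pixels.
#' @param datasetSpec spec for synthetic data (see [lesionDatasetSpec()]);
#'   ignored when a dataset is supplied to [runPipeline()].
#' @param backboneWidth width multiplier shared by the three backbones.
#' @param cvae list of classifier settings (`lr`, `epochs`, `batchSize`,
#'   `dropout`, `latentDim`, `hidden`).
#' @param splits train fractions to evaluate (default `c(0.8, 0.7)`).
#' @param ho list of tuning settings (`M`, `maxIter`, `epochs` used per
#'   tuning evaluation).
#' @return config list.
#' @export
pipelineConfig <- function(seed = 1L, blockSize = 16L, imageSize = 64L,
                           datasetSpec = NULL,
                           backboneWidth = 1,
                           cvae = list(), splits = c(0.8, 0.7),
                           ho = list()) {
  cv <- utils::modifyList(list(lr = 0.01, epochs = 50L, batchSize = 5L,
                               dropout = 0.5, latentDim = 8L,
                               hidden = c(64L, 32L)), cvae)
  hoCfg <- utils::modifyList(list(M = 8L, maxIter = 10L, epochs = 10L),
                             ho)
  if (is.null(datasetSpec))
    datasetSpec <- lesionDatasetSpec(seed = derivedSeed(seed, 1L))
  list(seed = as.integer(seed), blockSize = as.integer(blockSize),
       imageSize = as.integer(imageSize), datasetSpec = datasetSpec,
       backboneWidth = backboneWidth, cvae = cv, splits = splits,
       ho = hoCfg)
}

# encrypt/decrypt every image, verify bit-exactness, and PNG-round-trip
# the first ciphertext as a storage smoke check
verifyCipherStage <- function(imgs, config) {
  keySeed <- derivedSeed(config$seed, 2L)
  ok <- TRUE
  for (i in seq_along(imgs)) {
    enc <- encryptImage(imgs[[i]], keys = derivedSeed(keySeed, i),
                        blockSize = config$blockSize)
    dec <- decryptImage(enc, keys = derivedSeed(keySeed, i),
                        blockSize = config$blockSize)
    if (!identical(dec, imgs[[i]])) { ok <- FALSE; break }
    if (i == 1L) {
      tf <- tempfile(fileext = ".png")
      writeImagePNG(enc, tf)
      rt <- readImagePNG(tf)
      unlink(tf)
      dec2 <- decryptImage(rt, keys = derivedSeed(keySeed, i),
                           blockSize = config$blockSize)
      if (!identical(dec2, imgs[[i]])) ok <- FALSE
    }
  }
  ok
}

buildFusedFeatures <- function(imgs, config) {
  fams <- c("mobilenet", "inception", "alexnet")
  mats <- lapply(seq_along(fams), function(j) {
    bb <- buildBackbone(fams[j], inputSize = config$imageSize,
                        width = config$backboneWidth,
                        seed = derivedSeed(config$seed, 10L + j))
    extractFeatureMatrix(bb, imgs)
  })
  fuseFeatureMatrices(mats)
}

trainEvalSplit <- function(X, y, K, frac, config, cv = config$cvae) {
  sseed <- derivedSeed(config$seed, round(100 * frac))
  idx <- stratifiedIndex(y, frac, sseed)
  scaler <- fitFeatureScaler(X[idx$train, , drop = FALSE])
  Xtr <- applyFeatureScaler(X[idx$train, , drop = FALSE], scaler)
  Xte <- applyFeatureScaler(X[idx$test, , drop = FALSE], scaler)
  model <- newCVAE(ncol(X), K, latentDim = cv$latentDim,
                   hidden = cv$hidden,
                   seed = derivedSeed(config$seed, 20L + round(10 * frac)))
  model <- trainCVAE(model, Xtr, y[idx$train], lr = cv$lr,
                     epochs = cv$epochs, batchSize = cv$batchSize,
                     dropout = cv$dropout,
                     seed = derivedSeed(config$seed, 30L + round(10 * frac)))
  predTr <- classifyCVAE(model, Xtr)$labels
  predTe <- classifyCVAE(model, Xte)$labels
  cmTr <- confusionMatrix(y[idx$train], predTr, K)
  cmTe <- confusionMatrix(y[idx$test], predTe, K)
  list(train = metricReport(cmTr), test = metricReport(cmTe),
       cmTrain = cmTr, cmTest = cmTe, model = model, scaler = scaler,
       idx = idx)
}

# stratified index split on a plain label vector
stratifiedIndex <- function(y, frac, seed) {
  trainIdx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (k in sort(unique(y))) {
      idx <- which(y == k)
      nTr <- min(max(1L, as.integer(round(frac * length(idx)))),
                 length(idx) - 1L)
      trainIdx <- c(trainIdx, sample(idx, nTr))
    }
  })
  trainIdx <- sort(trainIdx)
  list(train = trainIdx, test = setdiff(seq_along(y), trainIdx))
}

#' Run the full privacy-preserving classification pipeline
#'
#' Stages, in order: (1) obtain data (synthetic generation or a labelled
#' image directory); (2) encrypt and decrypt every image, asserting the
#' bit-exact round trip (plus a lossless PNG storage round trip), so the
#' features computed afterwards provably equal those of the never-
#' encrypted images; (3) extract features with the three backbones and
#' fuse them; (4) for each configured split, standardize on the training
#' part, train the conditional VAE and evaluate per-class metrics on both
#' parts. Deterministic under the config's global seed.
#'
#' @param config from [pipelineConfig()].
#' @param dataset optional [LesionDataset-class]; default generates one
#'   from `config$datasetSpec`.
#' @param dataDir optional directory of PNGs + labels.csv (used when
#'   `dataset` is NULL and a directory is given).
#' @return list with `reports` (per split: `train` / `test` metric
#'   data.frames plus confusion matrices), `roundtripExact` (logical,
#'   always asserted TRUE), `featureDim`, `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), dataset = NULL,
                        dataDir = NULL) {
  if (is.null(dataset)) {
    dataset <- if (!is.null(dataDir)) readLesionDirectory(dataDir)
    else generateLesionDataset(config$datasetSpec)
  }
  imgs <- images(dataset)
  y <- labels(dataset)
  K <- dataset@K
  ok <- verifyCipherStage(imgs, config)
  if (!ok) stop("cipher stage: encrypt/decrypt round trip was not exact")
  X <- buildFusedFeatures(imgs, config)
  reports <- lapply(config$splits, function(frac)
    trainEvalSplit(X, y, K, frac, config))
  names(reports) <- sprintf("train%d", round(100 * config$splits))
  list(reports = reports, roundtripExact = ok, featureDim = ncol(X),
       config = config)
}

#' Tune classifier hyperparameters with hippopotamus optimization
#'
#' Searches a mixed box over (log10 learning rate, latent dimension,
#' batch size, dropout); integer dimensions are rounded at evaluation.
#' The objective is the negative validation macro precision: a validation
#' part is carved out of the supplied training features (stratified
#' 80/20), the CVAE is trained at the candidate settings and scored on
#' the validation part. The default configuration is seeded into the
#' initial population, so the tuned result never scores worse than the
#' default on the tuning objective.
#'
#' @param X training feature matrix (rows = samples).
#' @param y integer labels `1..K`.
#' @param K number of classes.
#' @param config pipeline config; `config$ho` holds `M`, `maxIter` and
#'   the per-evaluation epoch budget.
#' @param lowerBox,upperBox search box over `c(log10(lr), latentDim,
#'   batchSize, dropout)`.
#' @return list with `best` (decoded named settings), `bestFit`
#'   (negative validation macro precision), `trace` (per-iteration
#'   history) and `defaultFit`.
#' @export
tuneHyperparameters <- function(X, y, K, config = pipelineConfig(),
                                lowerBox = c(-3, 2, 2, 0),
                                upperBox = c(-1, 16, 16, 0.7)) {
  if (any(lowerBox >= upperBox)) stop("invalid search box")
  vseed <- derivedSeed(config$seed, 40L)
  idx <- stratifiedIndex(y, 0.8, vseed)
  scaler <- fitFeatureScaler(X[idx$train, , drop = FALSE])
  Xtr <- applyFeatureScaler(X[idx$train, , drop = FALSE], scaler)
  Xva <- applyFeatureScaler(X[idx$test, , drop = FALSE], scaler)
  decode <- function(p) list(
    lr = 10^p[1],
    latentDim = max(2L, min(as.integer(round(p[2])), ncol(X) - 1L)),
    batchSize = as.integer(round(p[3])),
    dropout = p[4])
  objective <- function(p) {
    s <- decode(p)
    model <- newCVAE(ncol(X), K, latentDim = s$latentDim,
                     hidden = config$cvae$hidden,
                     seed = derivedSeed(config$seed, 41L))
    model <- trainCVAE(model, Xtr, y[idx$train], lr = s$lr,
                       epochs = config$ho$epochs,
                       batchSize = s$batchSize, dropout = s$dropout,
                       seed = derivedSeed(config$seed, 42L))
    pred <- classifyCVAE(model, Xva)$labels
    precisionFitness(y[idx$test], pred, K)
  }
  defPoint <- c(log10(config$cvae$lr), config$cvae$latentDim,
                config$cvae$batchSize, config$cvae$dropout)
  defPoint <- clampBox(defPoint, lowerBox, upperBox)
  res <- hippoOptimize(objective, lowerBox, upperBox,
                       M = config$ho$M, maxIter = config$ho$maxIter,
                       seed = derivedSeed(config$seed, 43L),
                       init = matrix(defPoint, nrow = 1))
  list(best = decode(res$best), bestFit = res$bestFit,
       trace = res$history, defaultFit = objective(defPoint),
       evaluations = res$evaluations)
}
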