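# Shared fixtures and independent oracles, built in code.

randImage <- function(h, w, c = 3L, seed = 1L) {
  withr::with_seed(seed, {
    img <- array(sample(0:255, h * w * c, replace = TRUE), c(h, w, c))
    storage.mode(img) <- "integer"
    img
  })
}

# brute-force confusion matrix: explicit double loop
bruteConfusion <- function(yTrue, yPred, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cm[i, j] <- sum(yTrue == i & yPred == j)
  cm
}

# independent metric formulas written from first principles
bruteMetrics <- function(TP, TN, FP, FN) {
  tot <- TP + TN + FP + FN
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  m <- if (den > 0) (TP * TN - FP * FN) / den else 0
  c(accuracy = (TP + TN) / tot, precision = p, recall = r, fmeasure = f,
    mcc = m)
}

refTable <- function(name) {
  read.csv(system.file("extdata", name, package = "CipherLesion"))
}

# class-separated Gaussian feature benchmark: K classes, means 4 sigma
# apart on distinct axes, unit noise
gaussianFeatures <- function(n, K = 3L, d = 10L, sep = 4, seed = 1L) {
  mus <- matrix(0, K, d)
  for (k in 2:K) mus[k, k - 1] <- sep
  withr::with_seed(seed, {
    y <- rep(seq_len(K), length.out = n)
    X <- mus[y, , drop = FALSE] + matrix(rnorm(n * d), n, d)
  })
  list(X = X, y = y)
}
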