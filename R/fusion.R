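# Feature fusion: concatenation of per-backbone representations in the
# declared backbone order, with optional per-feature standardization whose
# statistics are fitted on training data only.

#' Fuse per-backbone feature vectors by concatenation
#'
#' Concatenates the vectors in the order given; the fused length is the
#' exact sum of the component lengths. A single vector passes through
#' unchanged.
#'
#' @param vectors non-empty list of numeric feature vectors.
#' @return fused numeric vector with `source = "fused"` attribute.
#' @export
#' @examples
#' length(fuseFeatures(list(rnorm(8), rnorm(16), rnorm(24))))  # 48
fuseFeatures <- function(vectors) {
  if (!length(vectors)) stop("need at least one feature vector")
  structure(unlist(lapply(vectors, as.numeric), use.names = FALSE),
            source = "fused")
}

#' Fuse per-backbone feature matrices by column binding
#'
#' @param mats non-empty list of numeric matrices with equal row counts
#'   (rows = samples), in declared backbone order.
#' @return fused matrix with `ncol` equal to the sum of component widths.
#' @export
fuseFeatureMatrices <- function(mats) {
  if (!length(mats)) stop("need at least one feature matrix")
  do.call(cbind, mats)
}

#' Fit a per-feature standardization scaler on training features
#'
#' @param X numeric training matrix (rows = samples).
#' @return list with `mean` and `sd` per feature (sd floored at 1e-8 so
#'   constant features map to 0 rather than NaN).
#' @export
fitFeatureScaler <- function(X) {
  list(mean = colMeans(X), sd = pmax(apply(X, 2, sd), 1e-8))
}

#' Apply a fitted standardization scaler
#'
#' @param X numeric matrix or vector.
#' @param scaler from [fitFeatureScaler()].
#' @return standardized matrix (training features get per-feature mean ~ 0
#'   and variance ~ 1; held-out features reuse the training statistics).
#' @export
applyFeatureScaler <- function(X, scaler) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
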