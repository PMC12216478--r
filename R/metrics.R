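# Confusion-matrix construction and the per-class metric suite
# (one-vs-rest accuracy, precision, recall, F-measure, MCC) with
# unweighted macro averaging. Zero-denominator convention: any metric
# whose denominator vanishes is defined as 0.

#' Build a K x K confusion matrix
#'
#' Rows are true classes, columns predicted classes; classes are integers
#' `1..K`. Empty inputs give the zero matrix.
#'
#' @param yTrue,yPred equal-length integer vectors of class labels in
#'   `1..K`.
#' @param K number of classes.
#' @return K x K integer matrix, `counts[i, j] = #(true = i, pred = j)`.
#' @export
#' @examples
#' confusionMatrix(c(1, 2, 2), c(1, 2, 1), K = 2)
confusionMatrix <- function(yTrue, yPred, K) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  K <- as.integer(K)
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length")
  if (length(yTrue) && (any(yTrue < 1L) || any(yTrue > K) ||
                        any(yPred < 1L) || any(yPred > K)))
    stop("labels out of range 1..", K)
  idx <- (yTrue - 1L) * K + yPred
  matrix(tabulate(idx, nbins = K * K), nrow = K, ncol = K, byrow = TRUE)
}

#' One-vs-rest binarization of a confusion matrix
#'
#' Reduces a K-class confusion matrix to the 2 x 2 counts for one class:
#' TP on the diagonal, FN the rest of its row, FP the rest of its column,
#' TN everything else. The four counts always sum to the sample total.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param class class index in `1..K`.
#' @return named numeric vector `c(TP, TN, FP, FN)`.
#' @export
binarizeClass <- function(cm, class) {
  K <- nrow(cm)
  stopifnot(class >= 1, class <= K)
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Metrics from binary counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F-measure `2PR/(P+R)` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric with a zero denominator is 0 by convention. Values are on
#' the `[0, 1]` scale (MCC in `[-1, 1]`).
#'
#' @param TP,TN,FP,FN nonnegative counts with a positive total.
#' @return named numeric vector
#'   `c(accuracy, precision, recall, fmeasure, mcc)`.
#' @export
#' @examples
#' classMetrics(7, 0, 3, 0)["precision"]  # 0.7
classMetrics <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion counts")
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  total <- TP + TN + FP + FN
  safe <- function(num, den) if (den > 0) num / den else 0
  acc <- (TP + TN) / total
  prec <- safe(TP, TP + FP)
  rec <- safe(TP, TP + FN)
  f <- fMeasure(prec, rec)
  den2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den2 > 0) (as.numeric(TP) * TN - as.numeric(FP) * FN) /
    sqrt(den2) else 0
  c(accuracy = acc, precision = prec, recall = rec, fmeasure = f, mcc = mcc)
}

#' Harmonic-mean F-measure
#'
#' `2PR/(P+R)`, 0 when `P + R = 0`. Scale-invariant: works equally on
#' fractions or percentages.
#'
#' @param precision,recall nonnegative values on a common scale.
#' @return F-measure on the same scale.
#' @export
#' @examples
#' fMeasure(77.78, 93.33)  # 84.85 (to 2 dp)
fMeasure <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Per-class metric report from a confusion matrix
#'
#' One-vs-rest binarizes every class and computes the full metric set.
#' Per-class "accuracy" here is the one-vs-rest binary accuracy, which is
#' why it can approach 1 for every class of a many-class problem.
#'
#' @param cm K x K confusion matrix.
#' @return data.frame with one row per class (columns `class`, `accuracy`,
#'   `precision`, `recall`, `fmeasure`, `mcc`), values in `[0, 1]`.
#' @export
metricReport <- function(cm) {
  K <- nrow(cm)
  rows <- t(vapply(seq_len(K), function(c) {
    b <- binarizeClass(cm, c)
    classMetrics(b["TP"], b["TN"], b["FP"], b["FN"])
  }, numeric(5)))
  data.frame(class = seq_len(K), rows)
}

#' Unweighted macro average of a per-class report
#'
#' Arithmetic mean of each metric column over classes, matching how
#' per-class tables are summarised by an unweighted "Average" row.
#'
#' @param report data.frame from [metricReport()], or any data.frame of
#'   per-class metric columns (a `class` column, if present, is dropped).
#' @return named numeric vector of macro-averaged metrics.
#' @export
macroAverage <- function(report) {
  cols <- setdiff(names(report), "class")
  colMeans(report[cols])
}

#' Round half-up for table display
#'
#' Report tables round half-up to a fixed number of decimals (so 0.845
#' displays as 0.85); full precision is retained internally.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a metric report the way published per-class tables print
#'
#' Converts a fraction-scale report to percentages, appends the macro
#' "Average" row and rounds half-up to 2 decimals.
#'
#' @param report data.frame from [metricReport()].
#' @param digits decimal places (default 2).
#' @return data.frame in percent with an `Average` row.
#' @export
formatMetricReport <- function(report, digits = 2) {
  cols <- setdiff(names(report), "class")
  out <- report
  out[cols] <- lapply(report[cols], function(x) roundHalfUp(100 * x, digits))
  avg <- roundHalfUp(100 * macroAverage(report), digits)
  out$class <- as.character(out$class)
  rbind(out, data.frame(class = "Average", as.list(avg)))
}
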