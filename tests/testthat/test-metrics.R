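test_that("confusion matrix matches a double-loop counting oracle", {
  expect_identical(confusionMatrix(integer(0), integer(0), 3),
                   matrix(0L, 3, 3))
  eye <- diag(3)
  storage.mode(eye) <- "integer"
  expect_identical(confusionMatrix(c(1, 2, 3), c(1, 2, 3), 3), eye)
  withr::with_seed(8, {
    yt <- sample(1:5, 200, TRUE)
    yp <- sample(1:5, 200, TRUE)
  })
  expect_identical(confusionMatrix(yt, yp, 5), bruteConfusion(yt, yp, 5))
  expect_error(confusionMatrix(c(1, 6), c(1, 1), 5), "out of range")
  expect_error(confusionMatrix(1:3, 1:2, 3), "equal length")
})

test_that("one-vs-rest binarization conserves totals", {
  expect_equal(binarizeClass(matrix(c(5, 0, 0, 5), 2, byrow = TRUE), 1),
               c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(binarizeClass(matrix(c(3, 1, 2, 4), 2, byrow = TRUE), 1),
               c(TP = 3, TN = 4, FP = 2, FN = 1))
  withr::with_seed(9, cm <- matrix(rpois(49, 4), 7, 7))
  for (c in 1:7) expect_equal(sum(binarizeClass(cm, c)), sum(cm))
})

test_that("class metrics reproduce worked examples and closed identities", {
  # harmonic mean of printed precision/recall reproduces the printed F
  expect_equal(roundHalfUp(fMeasure(77.78, 93.33)), 84.85)
  # P = R implies F = P
  expect_equal(fMeasure(98.67, 98.67), 98.67)
  m <- classMetrics(1, 1, 1, 1)
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["mcc"]), 0)
  expect_equal(unname(classMetrics(7, 0, 3, 0)["precision"]), 0.7)
  # zero-denominator conventions
  z <- classMetrics(0, 5, 0, 5)
  expect_equal(unname(z["precision"]), 0)
  expect_equal(unname(z["fmeasure"]), 0)
  expect_error(classMetrics(0, 0, 0, 0), "empty")
})

test_that("metric suite agrees with the brute-force oracle on random matrices", {
  withr::with_seed(10, {
    for (rep in 1:200) {
      K <- sample(2:6, 1)
      cm <- matrix(rpois(K * K, 3), K, K)
      if (sum(cm) == 0) cm[1, 1] <- 1
      rep_df <- metricReport(cm)
      for (c in seq_len(K)) {
        b <- binarizeClass(cm, c)
        expect_equal(unlist(rep_df[c, -1]),
                     bruteMetrics(b["TP"], b["TN"], b["FP"], b["FN"]),
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("F lies between min and max of precision and recall; MCC is bounded", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      b <- rpois(4, 5)
      if (sum(b) == 0) next
      m <- classMetrics(b[1], b[2], b[3], b[4])
      if (m["precision"] + m["recall"] > 0) {
        expect_lte(m["fmeasure"], max(m["precision"], m["recall"]) + 1e-12)
        expect_gte(m["fmeasure"], min(m["precision"], m["recall"]) - 1e-12)
      }
      expect_lte(abs(m["mcc"]), 1 + 1e-12)
    }
  })
  # perfect predictions give MCC 1 on every class
  cm <- diag(c(3, 5, 7)); storage.mode(cm) <- "integer"
  expect_true(all(metricReport(cm)$mcc == 1))
})

test_that("macro averaging is the unweighted mean and formats like a report table", {
  df <- data.frame(class = 1:3, accuracy = c(0.9, 0.9, 0.9),
                   precision = c(1, 0.5, 0.75))
  avg <- macroAverage(df)
  expect_equal(unname(avg["accuracy"]), 0.9)
  expect_equal(unname(avg["precision"]), mean(c(1, 0.5, 0.75)))
  # identical rows: macro equals the row
  one <- data.frame(class = 1:4, precision = rep(0.8, 4))
  expect_equal(unname(macroAverage(one)["precision"]), 0.8)
  # rounding is half-up (base round() would give 0.12 here)
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(2.5, 0), 3)
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  fm <- formatMetricReport(metricReport(cm))
  expect_identical(fm$class[3], "Average")
  expect_true(all(fm$accuracy <= 100))
})
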