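test_that("dataset generation honours counts, labels and the seed", {
  spec <- lesionDatasetSpec(classCounts = c(2, 2, 2), imageSize = 32,
                            seed = 3)
  ds <- generateLesionDataset(spec)
  expect_length(ds, 6L)
  expect_identical(labels(ds), c(1L, 1L, 2L, 2L, 3L, 3L))
  ds2 <- generateLesionDataset(spec)
  expect_identical(images(ds), images(ds2))
  expect_true(all(vapply(images(ds), function(im)
    all(im >= 0L & im <= 255L), logical(1))))
  expect_error(lesionDatasetSpec(classCounts = c(2, 0)), "counts")
  expect_error(lesionDatasetSpec(separability = 1.5), "separability")
  # default counts follow the archive-shaped imbalance
  def <- lesionDatasetSpec(scale = 1)
  expect_identical(def$classCounts,
                   c(114L, 376L, 95L, 438L, 357L, 462L, 77L, 181L, 139L))
  expect_identical(sum(def$classCounts), 2239L)
})

test_that("separability controls whether classes are distinguishable", {
  mkMeanCol <- function(ds) t(vapply(images(ds), function(im)
    apply(im, 3, mean), numeric(3)))
  # high separability: nearest-centroid on mean colour beats chance
  hi <- generateLesionDataset(lesionDatasetSpec(
    classCounts = rep(12, 4), imageSize = 32, separability = 1, seed = 4))
  Mh <- mkMeanCol(hi); yh <- labels(hi)
  tr <- withr::with_seed(5, sort(unlist(lapply(split(seq_along(yh), yh),
                                               sample, 8))))
  cent <- sapply(1:4, function(k)
    colMeans(Mh[intersect(tr, which(yh == k)), , drop = FALSE]))
  pred <- apply(Mh[-tr, ], 1, function(v)
    which.min(colSums((cent - v)^2)))
  accHi <- mean(pred == yh[-tr])
  expect_gt(accHi, 1 / 4 + 0.2)
  # zero separability: classes are exchangeable, accuracy ~ chance
  lo <- generateLesionDataset(lesionDatasetSpec(
    classCounts = rep(12, 4), imageSize = 32, separability = 0, seed = 4))
  Ml <- mkMeanCol(lo); yl <- labels(lo)
  centL <- sapply(1:4, function(k)
    colMeans(Ml[intersect(tr, which(yl == k)), , drop = FALSE]))
  predL <- apply(Ml[-tr, ], 1, function(v)
    which.min(colSums((centL - v)^2)))
  expect_lt(abs(mean(predL == yl[-tr]) - 1 / 4), 0.3)
})

test_that("stratified splits partition the data and preserve proportions", {
  ds <- generateLesionDataset(lesionDatasetSpec(
    classCounts = rep(10, 3), imageSize = 16, seed = 6))
  sp <- splitDataset(ds, 0.8, seed = 7)
  expect_identical(tabulate(labels(sp$train), 3), rep(8L, 3))
  expect_identical(tabulate(labels(sp$test), 3), rep(2L, 3))
  expect_identical(sort(c(sp$trainIdx, sp$testIdx)), seq_len(30L))
  expect_length(intersect(sp$trainIdx, sp$testIdx), 0L)
  # archive-shaped counts keep proportions within rounding
  big <- generateLesionDataset(lesionDatasetSpec(scale = 0.1,
                                                 imageSize = 16, seed = 8))
  sp2 <- splitDataset(big, 0.7, seed = 9)
  n_k <- tabulate(labels(big), big@K)
  t_k <- tabulate(labels(sp2$train), big@K)
  expect_true(all(abs(t_k - 0.7 * n_k) <= 1))
  # degenerate class blocks stratification
  tiny <- generateLesionDataset(lesionDatasetSpec(
    classCounts = c(4, 1), imageSize = 16, seed = 10))
  expect_error(splitDataset(tiny, 0.8), "2 images per class")
  expect_error(splitDataset(ds, 1.2), "trainFraction")
})

test_that("fixtures round-trip through PNG files and the directory loader", {
  ds <- generateLesionDataset(lesionDatasetSpec(
    classCounts = c(3, 2), imageSize = 24, seed = 11))
  outdir <- withr::local_tempdir()
  man <- writeFixtures(ds, outdir)
  expect_identical(man$n, 5L)
  expect_length(man$files, 5L)
  expect_true(file.exists(file.path(outdir, "labels.csv")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  back <- readLesionDirectory(outdir)
  expect_identical(labels(back), labels(ds))
  for (i in seq_len(5))
    expect_identical(images(back)[[i]], images(ds)[[i]])
  expect_identical(back@K, 2L)
})
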