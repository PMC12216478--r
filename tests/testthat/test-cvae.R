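test_that("KL divergence matches the closed form and is nonnegative", {
  expect_equal(klGaussian(rep(0, 5), rep(1, 5)), 0)
  expect_equal(klGaussian(1, 1), 0.5)
  expect_equal(klGaussian(0, 4), 0.5 * (4 - 1 - log(4)))
  withr::with_seed(1, {
    for (i in 1:50) {
      d <- sample(1:8, 1)
      mu <- rnorm(d); s2 <- exp(rnorm(d))
      expect_gte(klGaussian(mu, s2), 0)
    }
  })
  expect_error(klGaussian(0, 0), "positive")
})

test_that("reparameterization is mu + sigma * noise", {
  expect_equal(reparameterize(c(1, 2), c(1, 4), c(0, 0)), c(1, 2))
  withr::with_seed(2, eps <- rnorm(4))
  expect_equal(reparameterize(rep(0, 4), rep(1, 4), eps), eps)
  expect_equal(reparameterize(3, 4, 1.5), 3 + 2 * 1.5)
  # CLT bound: sample mean of many draws concentrates on mu
  withr::with_seed(3, z <- reparameterize(2, 0.25, rnorm(1e5)))
  expect_lt(abs(mean(z) - 2), 3 * 0.5 / sqrt(1e5))
  expect_error(reparameterize(0, -1, 0), "positive")
})

test_that("encoder output is deterministic with strictly positive variance", {
  m <- newCVAE(6, 3, latentDim = 3, seed = 4)
  x <- withr::with_seed(5, rnorm(6))
  e1 <- encodeCVAE(m, x, 2)
  e2 <- encodeCVAE(m, x, 2)
  expect_identical(e1, e2)
  expect_true(all(e1$sigma2 > 0))
  expect_true(all(is.finite(e1$mu)))
  expect_error(encodeCVAE(m, x, 9), "out of range")
  expect_error(newCVAE(4, 3, latentDim = 4), "latent")
})

test_that("the loss decomposes into reconstruction plus KL with the stated forms", {
  m <- newCVAE(5, 2, latentDim = 2, hidden = c(6, 4), seed = 6)
  x <- withr::with_seed(7, rnorm(5))
  noise <- withr::with_seed(8, rnorm(2))
  lb <- cvaeLoss(m, x, 1, noise)
  expect_equal(lb$total, lb$reconstruction + lb$kl)
  expect_gte(lb$kl, 0)
  expect_gte(lb$reconstruction, 0)
  # term-by-term oracle: replicate the forward pass with plain matrix code
  p <- m@par
  rl <- function(v) v * (v > 0)
  a0 <- c(x, 1, 0)
  h1 <- rl(p$W1 %*% a0 + p$b1)
  h2 <- rl(p$W2 %*% h1 + p$b2)
  mu <- as.numeric(p$Wm %*% h2 + p$bm)
  lv <- as.numeric(p$Wv %*% h2 + p$bv)
  z <- mu + exp(lv / 2) * noise
  g0 <- c(z, 1, 0)
  u1 <- rl(p$V1 %*% g0 + p$c1)
  u2 <- rl(p$V2 %*% u1 + p$c2)
  xhat <- as.numeric(p$Vo %*% u2 + p$co)
  expect_equal(lb$reconstruction, 0.5 * sum((x - xhat)^2))
  expect_equal(lb$kl, klGaussian(mu, exp(lv)))
})

test_that("backpropagated gradients match finite differences", {
  m <- newCVAE(6, 3, latentDim = 3, hidden = c(5, 4), seed = 2)
  par <- m@par
  withr::with_seed(3, {
    X <- matrix(rnorm(12), 6, 2)
    eps <- matrix(rnorm(6), 3, 2)
  })
  C <- CipherLesion:::oneHot(c(1, 3), 3)
  fw <- CipherLesion:::cvaeForward(par, X, C, eps, 0)
  gr <- CipherLesion:::cvaeBackward(par, X, C, fw)
  h <- 1e-6
  for (nm in names(par)) {
    for (ii in seq_len(min(4, length(par[[nm]])))) {
      p2 <- par
      p2[[nm]][ii] <- p2[[nm]][ii] + h
      up <- CipherLesion:::cvaeForward(p2, X, C, eps, 0)$loss
      p2[[nm]][ii] <- p2[[nm]][ii] - 2 * h
      dn <- CipherLesion:::cvaeForward(p2, X, C, eps, 0)$loss
      expect_equal(gr[[nm]][ii], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible, records history and reduces the loss", {
  gb <- gaussianFeatures(120, K = 2, d = 8, sep = 4, seed = 10)
  sc <- fitFeatureScaler(gb$X)
  Xs <- applyFeatureScaler(gb$X, sc)
  m0 <- newCVAE(8, 2, latentDim = 3, seed = 1)
  expect_error(trainCVAE(m0, matrix(numeric(0), 0, 8), integer(0)), "empty")
  m1 <- trainCVAE(m0, Xs, gb$y, epochs = 20, seed = 5)
  m2 <- trainCVAE(m0, Xs, gb$y, epochs = 20, seed = 5)
  expect_identical(m1@history, m2@history)
  expect_equal(nrow(m1@history), 20L)
  expect_lt(mean(tail(m1@history$loss, 3)), mean(head(m1@history$loss, 3)))
  expect_true(m1@trained)
})

test_that("classification is a deterministic argmin with low-index tie-break", {
  expect_identical(CipherLesion:::decideClass(matrix(c(1, 2), 1)), 1L)
  expect_identical(CipherLesion:::decideClass(matrix(c(2, 1), 1)), 2L)
  expect_identical(CipherLesion:::decideClass(matrix(c(3, 3, 3), 1)), 1L)
  m0 <- newCVAE(8, 2, latentDim = 3, seed = 1)
  expect_error(classifyCVAE(m0, matrix(0, 1, 8)), "trained")
  gb <- gaussianFeatures(160, K = 2, d = 8, sep = 4, seed = 11)
  sc <- fitFeatureScaler(gb$X)
  Xs <- applyFeatureScaler(gb$X, sc)
  tr <- withr::with_seed(12, sample(160, 120))
  m <- trainCVAE(m0, Xs[tr, ], gb$y[tr], epochs = 30, seed = 2)
  out1 <- classifyCVAE(m, Xs[-tr, ])
  out2 <- classifyCVAE(m, Xs[-tr, ])
  expect_identical(out1, out2)
  expect_identical(dim(out1$scores), c(40L, 2L))
  expect_gt(mean(out1$labels == gb$y[-tr]), 0.85)
  # encoders separate the classes after training on separated data
  e1 <- encodeCVAE(m, Xs[1, ], 1)
  e2 <- encodeCVAE(m, Xs[1, ], 2)
  expect_false(isTRUE(all.equal(e1$mu, e2$mu)))
})
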