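test_that("key derivation is deterministic, complete and balanced", {
  expect_identical(deriveKeys(0, 1)@k1, 1L)
  a <- deriveKeys(42, 64)
  b <- deriveKeys(42, 64)
  expect_identical(a@k1, b@k1)
  expect_identical(a@k2, b@k2)
  expect_identical(a@k3, b@k3)
  expect_identical(a@k4, b@k4)
  expect_false(identical(deriveKeys(43, 64)@k1, a@k1))
  expect_error(deriveKeys(1, 0), "positive")
  # inversion flags are Bernoulli(0.5): binomial bound at n = 1e4
  big <- deriveKeys(7, 1e4)
  expect_lt(abs(mean(big@k3) - 0.5), 0.02)
  # k1 is always a bijection
  for (s in 1:5) expect_setequal(deriveKeys(s, 50)@k1, 1:50)
})

test_that("partitioning tiles exactly and reassembly is the identity", {
  img <- array(0L, c(32, 32, 3))
  expect_length(partitionImage(img, 16)$blocks, 4L)
  expect_length(partitionImage(array(0L, c(256, 256, 3)), 16)$blocks, 256L)
  rnd <- randImage(48, 80, seed = 5)
  p <- partitionImage(rnd, 16)
  expect_identical(reassembleImage(p$blocks, p$partition), rnd)
  err <- tryCatch(partitionImage(randImage(50, 64), 16), error = identity)
  expect_match(conditionMessage(err), "height 50")
  # reflect padding round-trips through the partition metadata
  odd <- randImage(50, 70, seed = 6)
  pp <- partitionImage(odd, 16, pad = TRUE)
  expect_true(pp$partition@padded)
  expect_identical(reassembleImage(pp$blocks, pp$partition), odd)
})

test_that("negative-positive transform matches the XOR oracle and is an involution", {
  withr::with_seed(1, p <- sample(0:255, 200, TRUE))
  blk <- array(as.integer(p), c(10, 20, 1))
  out <- negposTransform(blk, 1)
  expect_identical(as.integer(out), bitwXor(as.integer(p), 255L))
  expect_identical(negposTransform(blk, 0), blk)
  expect_identical(negposTransform(out, 1), blk)
  expect_identical(negposTransform(array(0L, c(1, 1, 1)), 1)[1], 255L)
  expect_identical(negposTransform(array(100L, c(1, 1, 1)), 1)[1], 155L)
  # 4-bit depth
  expect_identical(negposTransform(array(5L, c(1, 1, 1)), 1, bitDepth = 4)[1],
                   10L)
})

test_that("dihedral transforms realize all 8 square symmetries with exact inverses", {
  m <- matrix(1:9, 3, 3)
  outs <- lapply(0:7, function(k) dihedralTransform(m, k))
  # identity, distinctness, multiset preservation
  expect_identical(outs[[1]], m)
  expect_equal(length(unique(outs)), 8L)
  for (o in outs) expect_setequal(as.integer(o), 1:9)
  # independent oracle: the 8 symmetries as explicit index remappings
  expected <- list(m, t(m)[3:1, ], m[3:1, 3:1], t(m)[, 3:1],
                   m[, 3:1], t(m), m[3:1, ], t(m)[3:1, 3:1])
  for (o in outs)
    expect_true(any(vapply(expected, identical, logical(1), o)))
  # group order: four quarter-turns = identity
  r <- m
  for (i in 1:4) r <- dihedralTransform(r, 1)
  expect_identical(r, m)
  # inverse table
  blk <- randImage(16, 16, seed = 2)
  for (k in 0:7)
    expect_identical(
      dihedralTransform(dihedralTransform(blk, k), dihedralInverse(k)), blk)
  expect_error(dihedralTransform(matrix(1:6, 2, 3), 1), "square")
})

test_that("channel shuffling enumerates the 6 permutations with inverses", {
  blk <- array(0L, c(2, 2, 3))
  blk[, , 1] <- 10L; blk[, , 2] <- 20L; blk[, , 3] <- 30L
  outs <- lapply(1:6, function(k) shuffleChannels(blk, k))
  expect_identical(outs[[1]], blk)
  expect_equal(length(unique(outs)), 6L)
  for (k in 1:6)
    expect_identical(
      shuffleChannels(shuffleChannels(blk, k), shuffleChannelsInverse(k)),
      blk)
  expect_error(shuffleChannels(array(0L, c(2, 2, 1)), 2), "3-channel")
})

test_that("encryption composes the four steps and decryption inverts bit-exactly", {
  img <- randImage(64, 64, seed = 10)
  # all-identity key set: cipher is a no-op
  expect_identical(encryptImage(img, identityKeys(16), 16), img)
  # shape/bit-depth preservation and actual scrambling
  enc <- encryptImage(img, keys = 11, blockSize = 16)
  expect_identical(dim(enc), dim(img))
  expect_true(all(enc >= 0L & enc <= 255L))
  expect_gt(mean(enc != img), 0.5)
  expect_identical(decryptImage(enc, keys = 11, blockSize = 16), img)
  # K1+K2 only: global per-channel histograms unchanged
  keys <- deriveKeys(5, 16)
  k12 <- new("KeySet", masterSeed = 5L, k1 = keys@k1, k2 = keys@k2,
             k3 = integer(16), k4 = rep(1L, 16))
  e <- encryptImage(img, k12, 16)
  for (ch in 1:3)
    expect_identical(tabulate(e[, , ch] + 1L, 256),
                     tabulate(img[, , ch] + 1L, 256))
  # K1 moves blocks without altering them
  p0 <- partitionImage(img, 16)$blocks
  k1only <- new("KeySet", masterSeed = 5L, k1 = keys@k1,
                k2 = integer(16), k3 = integer(16), k4 = rep(1L, 16))
  p1 <- partitionImage(encryptImage(img, k1only, 16), 16)$blocks
  expect_true(all(vapply(p1, function(b)
    any(vapply(p0, identical, logical(1), b)), logical(1))))
  # mismatched key set size
  expect_error(encryptImage(img, deriveKeys(1, 4), 16), "key set")
})

test_that("decryption with the wrong key does not recover the plaintext", {
  img <- randImage(48, 48, seed = 20)
  for (s in 1:10) {
    enc <- encryptImage(img, keys = s, blockSize = 16)
    wrong <- decryptImage(enc, keys = s + 100, blockSize = 16)
    expect_gt(mean(abs(wrong - img)), 0)
    expect_identical(decryptImage(enc, keys = s, blockSize = 16), img)
  }
})

test_that("grayscale images encrypt and decrypt without a channel step", {
  img <- randImage(32, 32, c = 1L, seed = 30)
  enc <- encryptImage(img, keys = 3, blockSize = 8)
  expect_identical(dim(enc), dim(img))
  expect_identical(decryptImage(enc, keys = 3, blockSize = 8), img)
})

test_that("padded encryption round-trips and crops back to the original size", {
  img <- randImage(50, 70, seed = 40)
  enc <- encryptImage(img, keys = 9, blockSize = 16, pad = TRUE)
  expect_identical(dim(enc)[1:2], c(64L, 80L))
  dec <- decryptImage(enc, keys = 9, blockSize = 16)
  expect_identical(dec, img)
})

test_that("ciphertext survives a lossless PNG storage round trip", {
  img <- randImage(64, 64, seed = 50)
  enc <- encryptImage(img, keys = 12, blockSize = 16)
  tf <- withr::local_tempfile(fileext = ".png")
  writeImagePNG(enc, tf)
  back <- readImagePNG(tf)
  expect_identical(back, array(as.integer(enc), dim(enc)))
  expect_identical(decryptImage(back, keys = 12, blockSize = 16), img)
})
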