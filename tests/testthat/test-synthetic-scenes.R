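test_that("a null scene (all amplitudes zero) is the zero map", {
  p <- sceneParams(imageSize = c(32L, 32L), nCellBodies = 0L, nRidges = 0L,
                   backgroundTilt = 0, textureAmplitude = 0,
                   lineNoiseSd = 0, pixelNoiseSd = 0, seed = 1)
  expect_equal(heights(generateScene(p)), matrix(0, 32, 32))
})

test_that("scene generation is deterministic per seed and leaves the RNG alone", {
  p <- sceneParams(imageSize = c(48L, 48L), bodyRadiusRange = c(6, 15), seed = 42)
  set.seed(777)
  before <- .Random.seed
  h1 <- generateScene(p)
  expect_identical(.Random.seed, before)
  h2 <- generateScene(p)
  expect_identical(heights(h1), heights(h2))
  p2 <- p
  p2@seed <- 43
  expect_false(identical(heights(h1), heights(generateScene(p2))))
})

test_that("a single noiseless cell body peaks within the requested height range", {
  for (seed in 1:5) {
    p <- sceneParams(imageSize = c(64L, 64L), nCellBodies = 1L,
                     bodyHeightRange = c(1, 5), bodyRadiusRange = c(8, 16),
                     nRidges = 0L, backgroundTilt = 0, textureAmplitude = 0,
                     lineNoiseSd = 0, pixelNoiseSd = 0, seed = seed)
    mx <- max(heights(generateScene(p)))
    expect_gte(mx, 1 - 1e-6)
    expect_lte(mx, 5 + 1e-6)
  }
})

test_that("scars displace exactly the selected rows and report exact ground truth", {
  h <- smallScene(seed = 3)
  s <- scarSpec(nScars = 2L, scarRows = c(10, 30), scarOffsetRange = c(1, 1),
                seed = 9)
  out <- addScars(h, s)
  d <- heights(out$scarred) - heights(h)
  changed <- which(rowSums(d != 0) > 0)
  expect_identical(changed, c(10L, 30L))
  expect_identical(which(!maskKeep(out$mask)), c(10L, 30L))
  # untouched rows bit-identical
  expect_identical(heights(out$scarred)[-changed, ], heights(h)[-changed, ])
  # same seed, same placement
  out2 <- addScars(h, s)
  expect_identical(heights(out$scarred), heights(out2$scarred))
})

test_that("zero scars is the identity with an all-keep mask", {
  h <- smallScene(seed = 4)
  out <- addScars(h, scarSpec(nScars = 0L))
  expect_identical(heights(out$scarred), heights(h))
  expect_true(all(maskKeep(out$mask)))
})

test_that("scar rows out of range are a parameter error", {
  h <- smallScene(seed = 4)
  expect_error(addScars(h, scarSpec(nScars = 1L, scarRows = 99)),
               class = "ps_parameter_error")
})

test_that("datasets are reproducible, extensible and scene-wise independent", {
  p <- sceneParams(imageSize = c(32L, 32L), bodyRadiusRange = c(4, 10), seed = 0)
  d3 <- generateDataset(3, p, seed = 11)
  d3b <- generateDataset(3, p, seed = 11)
  d5 <- generateDataset(5, p, seed = 11)
  for (k in 1:3) {
    expect_identical(heights(d3[[k]]), heights(d3b[[k]]))
    expect_identical(heights(d3[[k]]), heights(d5[[k]]))  # extensible prefix
  }
  expect_false(identical(heights(d3[[1]]), heights(d3[[2]])))
  # n = 1 equals generateScene at sub-seed 0
  p1 <- p
  p1@seed <- as.numeric(PartialScan:::subSeed(11, 0))
  expect_identical(heights(generateDataset(1, p, seed = 11)[[1]]),
                   heights(generateScene(p1)))
})

test_that("a dataset's heights span the configured body height range", {
  p <- sceneParams(imageSize = c(32L, 32L), bodyRadiusRange = c(4, 10))
  d <- generateDataset(60, p, seed = 2)
  peaks <- vapply(d, function(h) max(heights(h)), numeric(1))
  expect_gt(max(peaks), 3)    # tall scenes occur
  expect_gt(mean(peaks >= 1), 0.9)  # bodies of at least the minimum height
})
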