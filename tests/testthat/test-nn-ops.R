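# The partial-convolution primitive and the compiled layer kernels, checked
# against hand computations and the pure-R reference implementations.

test_that("a fully valid window reduces to the standard convolution", {
  set.seed(1)
  v <- matrix(rnorm(9), 3)
  k <- matrix(rnorm(9), 3)
  r <- partialConv(v, matrix(1, 3, 3), k, bias = 0.7)
  expect_equal(r$value, sum(k * v) + 0.7)
  expect_identical(r$maskBit, 1)
})

test_that("an all-invalid window outputs zero with a zero mask bit", {
  r <- partialConv(matrix(5, 3, 3), matrix(0, 3, 3), matrix(1, 3, 3), bias = 2)
  expect_identical(r$value, 0)
  expect_identical(r$maskBit, 0)
})

test_that("a partially valid window rescales by size over valid count", {
  v <- matrix(0, 3, 3); m <- matrix(0, 3, 3); k <- matrix(0, 3, 3)
  v[1, 1] <- 2; v[2, 3] <- -1; v[3, 2] <- 4
  m[1, 1] <- 1; m[2, 3] <- 1; m[3, 2] <- 1
  k[1, 1] <- 0.5; k[2, 3] <- 1.5; k[3, 2] <- -0.25
  hand <- (0.5 * 2 + 1.5 * (-1) + (-0.25) * 4) * (9 / 3) + 0.1
  r <- partialConv(v, m, k, bias = 0.1)
  expect_equal(r$value, hand)
  expect_identical(r$maskBit, 1)
  expect_error(partialConv(v, m[1:2, ], k), class = "ps_dimension_error")
})

test_that("compiled layer kernels match the pure-R reference implementations", {
  withr::local_options(PartialScan.doublePrecision = TRUE)
  set.seed(20)
  x <- array(runif(14 * 11 * 3), c(14, 11, 3))
  mask <- matrix(rbinom(14 * 11, 1, 0.7), 14, 11)
  W <- matrix(rnorm(27 * 4), 27, 4)
  b <- rnorm(4)
  fc <- PartialScan:::.pconvForward(x, mask, W, b)
  fr <- PartialScan:::.pconvForwardR(x, mask, W, b)
  expect_equal(fc$out, fr$out, tolerance = 1e-12)
  expect_equal(fc$newMask, fr$newMask)
  dOut <- array(rnorm(14 * 11 * 4), c(14, 11, 4))
  bc <- PartialScan:::.pconvBackward(dOut, fc$cache, W)
  br <- PartialScan:::.pconvBackwardR(dOut, fr$cache, W)
  expect_equal(bc$dx, br$dx, tolerance = 1e-12)
  expect_equal(bc$dW, br$dW, tolerance = 1e-12)
  expect_equal(bc$db, as.numeric(br$db), tolerance = 1e-12)

  x2 <- array(rnorm(12 * 10 * 5), c(12, 10, 5))
  pc <- PartialScan:::.poolForward(x2)
  pr <- PartialScan:::.poolForwardR(x2)
  expect_equal(pc$out, pr$out)
  expect_equal(as.vector(pc$choice), as.vector(pr$choice))
  dP <- array(rnorm(6 * 5 * 5), c(6, 5, 5))
  expect_equal(PartialScan:::.poolBackward(dP, pc),
               PartialScan:::.poolBackwardR(dP, pr))
  expect_equal(PartialScan:::.upsampleForward(x2),
               PartialScan:::.upsampleForwardR(x2))
  d2 <- array(rnorm(12 * 10 * 5), c(12, 10, 5))
  expect_equal(PartialScan:::.upsampleBackward(d2),
               PartialScan:::.upsampleBackwardR(d2))
})

test_that("a full-image partial convolution layer matches the window primitive", {
  withr::local_options(PartialScan.doublePrecision = TRUE)
  set.seed(4)
  x <- array(runif(8 * 8), c(8, 8, 1))
  mask <- matrix(rbinom(64, 1, 0.6), 8, 8)
  W <- matrix(rnorm(9), 9, 1)
  b <- 0.3
  fw <- PartialScan:::.pconvForward(x, mask, W, b)
  kern <- matrix(W[, 1], 3, 3)  # slot order is column-major over (dr, dc)
  xp <- PartialScan:::padMatrix(x[, , 1], 1L)
  mp <- PartialScan:::padMatrix(mask, 1L)
  for (i in sample(8, 4)) {
    for (j in sample(8, 4)) {
      r <- partialConv(xp[i:(i + 2), j:(j + 2)], mp[i:(i + 2), j:(j + 2)],
                       kern, bias = b)
      expect_equal(fw$out[i, j, 1], r$value, tolerance = 1e-12)
      expect_equal(fw$newMask[i, j], r$maskBit)
    }
  }
})

test_that("network gradients match finite differences", {
  withr::local_options(PartialScan.doublePrecision = TRUE)
  set.seed(1)
  cfg <- modelConfig(arch = "partial_cnn", filters = c(3L, 4L), dropout = 0,
                     inputSize = c(16L, 16L))
  model <- buildModel(cfg, seed = 2)
  x <- matrix(runif(256), 16)
  mask <- matrix(1, 16, 16); mask[c(5, 6, 11), ] <- 0
  xm <- x; xm[c(5, 6, 11), ] <- 0
  truth <- matrix(runif(256), 16)
  lc <- lossConfig(alpha = 0.5, ssimWindow = 5L)
  fw <- PartialScan:::.forward(model@weights, cfg, xm, mask)
  dPred <- PartialScan:::.combinedLossGrad(truth, fw$pred, lc)
  gr <- PartialScan:::.backward(model@weights, cfg, fw$cache, dPred)
  lossAt <- function(w)
    combinedLoss(truth, PartialScan:::.forward(w, cfg, xm, mask)$pred, lc)
  eps <- 1e-6
  worst <- 0
  paths <- c("enc[[1]]$W", "enc[[2]]$W", "enc[[1]]$b", "bot$W", "bot$b",
             "dec[[1]]$W", "dec[[2]]$W", "dec[[2]]$b", "out$W", "out$b")
  for (e in paths) {
    arr <- eval(parse(text = paste0("model@weights$", e)))
    garr <- eval(parse(text = paste0("gr$", e)))
    for (t in 1:3) {
      ii <- sample(length(arr), 1)
      w <- model@weights
      eval(parse(text = sprintf("w$%s[%d] <- w$%s[%d] + eps", e, ii, e, ii)))
      lp <- lossAt(w)
      w <- model@weights
      eval(parse(text = sprintf("w$%s[%d] <- w$%s[%d] - eps", e, ii, e, ii)))
      lm_ <- lossAt(w)
      worst <- max(worst, abs((lp - lm_) / (2 * eps) - garr[ii]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("with an all-valid mask the partial network equals the plain network", {
  cfgP <- modelConfig(arch = "partial_cnn", filters = c(4L, 8L), dropout = 0,
                      inputSize = c(32L, 32L))
  cfgC <- modelConfig(arch = "cnn", filters = c(4L, 8L), dropout = 0,
                      inputSize = c(32L, 32L))
  model <- buildModel(cfgP, seed = 5)
  set.seed(6)
  x <- matrix(runif(32 * 32), 32)
  ones <- matrix(1, 32, 32)
  fP <- PartialScan:::.forward(model@weights, cfgP, x, ones)
  fC <- PartialScan:::.forward(model@weights, cfgC, x, ones)
  expect_lt(max(abs(fP$pred - fC$pred)), 1e-5)
})

test_that("architectures share the parameter count and output shape", {
  cfgP <- modelConfig(arch = "partial_cnn", filters = c(4L, 8L),
                      inputSize = c(32L, 32L))
  cfgC <- modelConfig(arch = "cnn", filters = c(4L, 8L), inputSize = c(32L, 32L))
  mP <- buildModel(cfgP, seed = 1)
  mC <- buildModel(cfgC, seed = 1)
  expect_lte(nParameters(mP), nParameters(mC))
  x <- matrix(runif(32 * 32), 32)
  m0 <- matrix(1, 32, 32)
  expect_identical(dim(PartialScan:::.forward(mP@weights, cfgP, x, m0)$pred),
                   c(32L, 32L))
  expect_identical(dim(PartialScan:::.forward(mC@weights, cfgC, x, m0)$pred),
                   c(32L, 32L))
})

test_that("input sizes not divisible by the pooling depth are rejected", {
  expect_error(modelConfig(filters = c(4L, 8L), inputSize = c(30L, 32L)),
               "divisible")
})


test_that("the single-precision compute path tracks the double path", {
  set.seed(30)
  x <- array(runif(24 * 20 * 6), c(24, 20, 6))
  mask <- matrix(rbinom(24 * 20, 1, 0.7), 24, 20)
  W <- matrix(rnorm(15 * 6 * 8, 0, 0.2), 15 * 6, 8)
  b <- rnorm(8)
  fD <- PartialScan:::.pconvForwardCpp(x, mask, W, b, 5L, 3L)
  fF <- PartialScan:::.pconvForwardCppF(x, mask, W, b, 5L, 3L)
  expect_lt(max(abs(fD$out - fF$out)) / max(abs(fD$out)), 1e-5)
  expect_identical(fD$newMask, fF$newMask)
  dOut <- array(rnorm(24 * 20 * 8), c(24, 20, 8))
  bD <- PartialScan:::.pconvBackwardCpp(dOut, x, mask, W, 5L, 3L)
  bF <- PartialScan:::.pconvBackwardCppF(dOut, x, mask, W, 5L, 3L)
  expect_lt(max(abs(bD$dx - bF$dx)) / max(abs(bD$dx)), 1e-5)
  expect_lt(max(abs(bD$dW - bF$dW)) / max(abs(bD$dW)), 1e-5)
  # two-group variant
  f2D <- PartialScan:::.pconvForward2Cpp(x, mask, 4L, 1 - mask, W, b, 5L, 3L)
  f2F <- PartialScan:::.pconvForward2CppF(x, mask, 4L, 1 - mask, W, b, 5L, 3L)
  expect_lt(max(abs(f2D$out - f2F$out)) / max(abs(f2D$out)), 1e-5)
})
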