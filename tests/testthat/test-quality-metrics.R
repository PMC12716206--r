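test_that("MSE and Pearson agree with brute-force computations", {
  set.seed(8)
  for (t in 1:3) {
    a <- matrix(runif(24 * 20), 24)
    b <- matrix(runif(24 * 20), 24)
    expect_equal(mseMetric(a, b), bruteMSE(a, b), tolerance = 1e-12)
    expect_equal(pearsonMetric(a, b), brutePearson(a, b), tolerance = 1e-12)
  }
  a <- matrix(runif(16), 4)
  expect_equal(mseMetric(a, a), 0)
  expect_equal(pearsonMetric(a, a), 1)
  expect_equal(pearsonMetric(a, 2 - a), -1)
  expect_error(pearsonMetric(matrix(1, 4, 4), a), class = "ps_undefined_error")
})

test_that("PSNR follows its closed form and is monotone in MSE", {
  a <- matrix(0, 10, 10)
  b01 <- a; b01[] <- 0.1        # mse 0.01
  expect_equal(psnrMetric(a, b01), 20)
  expect_equal(psnrMetric(a, a + 1), 0)  # mse 1
  expect_identical(psnrMetric(a, a), Inf)
  # monotone decreasing in mse at fixed maxI
  set.seed(1)
  x <- matrix(runif(100), 10)
  noise <- matrix(rnorm(100), 10)
  psnrs <- vapply(c(0.01, 0.05, 0.2), function(s) psnrMetric(x, x + s * noise),
                  numeric(1))
  expect_true(all(diff(psnrs) < 0))
  expect_error(psnrMetric(a, b01, maxI = 0), class = "ps_parameter_error")
})

test_that("SSIM matches a brute-force window loop and the reference defaults", {
  set.seed(9)
  x <- matrix(runif(20 * 18), 20)
  y <- matrix(runif(20 * 18), 20)
  expect_equal(ssimMetric(x, y), bruteSSIM(x, y, 7), tolerance = 1e-10)
  expect_equal(ssimMetric(x, x), 1)
  expect_error(ssimMetric(x, y[, 1:17]), class = "ps_dimension_error")
  expect_error(ssimMetric(x[1:5, 1:5], y[1:5, 1:5], window = 7),
               class = "ps_parameter_error")
})

test_that("SSIM agrees with the scikit-image implementation to 1e-6", {
  # cross-implementation oracle on 20 random pairs via the python interpreter
  set.seed(10)
  td <- withr::local_tempdir()
  rvals <- numeric(20)
  for (i in 1:20) {
    a <- matrix(runif(64 * 64), 64)
    b <- pmin(pmax(a + matrix(rnorm(64 * 64, 0, 0.1), 64), 0), 1)
    write.table(a, file.path(td, sprintf("a%02d.csv", i)), sep = ",",
                row.names = FALSE, col.names = FALSE)
    write.table(b, file.path(td, sprintf("b%02d.csv", i)), sep = ",",
                row.names = FALSE, col.names = FALSE)
    rvals[i] <- ssimMetric(a, b)
  }
  py <- c(
    "import sys, glob, numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    "d = sys.argv[1]",
    "for i in range(1, 21):",
    "    a = np.loadtxt(f'{d}/a{i:02d}.csv', delimiter=',')",
    "    b = np.loadtxt(f'{d}/b{i:02d}.csv', delimiter=',')",
    "    print('%.15f' % ssim(a, b, win_size=7, data_range=1.0))")
  pyf <- file.path(td, "ssim_ref.py")
  writeLines(py, pyf)
  out <- system2("python", c(pyf, td), stdout = TRUE)
  ref <- as.numeric(out)
  expect_identical(length(ref), 20L)
  expect_lt(max(abs(ref - rvals)), 1e-6)
})

test_that("anticorrelated binary patterns give negative SSIM", {
  ch <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_lt(ssimMetric(ch, 1 - ch, window = 7), 0)
})

test_that("edge density behaves like an edge fraction", {
  expect_equal(edgeDensity(matrix(0.5, 50, 50)), 0)
  # one sharp full-width horizontal step in a 100x100 image: about 1% edges
  step <- rbind(matrix(0, 50, 100), matrix(1, 50, 100))
  d <- edgeDensity(step)
  expect_gte(d, 0.005)
  expect_lte(d, 0.02)
  # smoothing removes fine edges
  set.seed(11)
  fine <- (outer(1:64, 1:64, function(i, j) (floor(i / 2) + floor(j / 2)) %% 2))
  blurred <- PartialScan:::gaussBlur(fine, 4)
  expect_gt(edgeDensity(fine), edgeDensity(blurred))
  # invariant to constant offsets
  img <- heights(normalizeMap(smallScene(seed = 12))) * 0.5
  expect_equal(edgeDensity(img), edgeDensity(img + 0.25))
})

test_that("the frequency-content ratio tracks high-frequency energy", {
  img <- heights(normalizeMap(smallScene(seed = 13)))
  expect_equal(frequencyRatio(img, img), 1)
  blurred <- PartialScan:::gaussBlur(img, 2)
  expect_lt(frequencyRatio(blurred, img), 1)
  set.seed(14)
  noisy <- img + matrix(rnorm(length(img), 0, 0.05), nrow(img))
  expect_gt(frequencyRatio(noisy, img), 1)
  expect_error(frequencyRatio(img, matrix(1, 48, 48)),
               class = "ps_undefined_error")
})

test_that("the identity pair produces the identity metric panel", {
  img <- heights(normalizeMap(smallScene(seed = 15)))
  rep <- evaluatePair(img, img)
  m <- metricMeans(rep)
  expect_equal(unname(m["mse"]), 0)
  expect_identical(unname(m["psnr"]), Inf)
  expect_equal(unname(m["ssim"]), 1)
  expect_equal(unname(m["pearson"]), 1)
  expect_equal(unname(m["freq_ratio"]), 1)
})

test_that("batch reports aggregate per-pair metrics with mean and SD", {
  imgs <- lapply(1:3, function(s) heights(normalizeMap(smallScene(seed = s))))
  recs <- lapply(imgs, function(x) pmin(pmax(x + 0.01, 0), 1))
  batch <- evaluateBatch(imgs, recs)
  expect_identical(batch@n, 3L)
  per <- vapply(1:3, function(i) mseMetric(imgs[[i]], recs[[i]]), numeric(1))
  expect_equal(metricMeans(batch)[["mse"]], mean(per))
  # identical pairs have zero SD
  same <- evaluateBatch(imgs[c(1, 1, 1)], recs[c(1, 1, 1)])
  expect_true(all(metricSummary(same)$sd == 0))
})
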