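test_that("CSV round trip is exact", {
  h <- HeightMap(matrix(c(0, 2, 1, 3), 2))
  f <- withr::local_tempfile(fileext = ".csv")
  writeHeightMap(h, f)
  r <- readHeightMap(f)
  expect_identical(heights(r), heights(h))

  set.seed(11)
  h2 <- HeightMap(matrix(runif(32 * 16, -4, 9), 32))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeHeightMap(h2, f2)
  expect_identical(heights(readHeightMap(f2)), heights(h2))
})

test_that("float TIFF round trip is stable at single precision", {
  set.seed(5)
  h <- HeightMap(matrix(runif(64 * 64), 64))
  f <- withr::local_tempfile(fileext = ".tif")
  writeHeightMap(h, f)
  r1 <- readHeightMap(f)
  # one pass quantizes doubles to float32 ...
  expect_lt(max(abs(heights(r1) - heights(h))), 2^-23)
  # ... after which the stored bit pattern round-trips identically
  writeHeightMap(r1, f)
  r2 <- readHeightMap(f)
  expect_identical(heights(r2), heights(r1))
})

test_that("png16 round trip is bounded by one 16-bit quantization step", {
  set.seed(6)
  h <- normalizeMap(HeightMap(matrix(runif(40 * 56, 0, 3), 40)))
  f <- withr::local_tempfile(fileext = ".png")
  writeHeightMap(h, f)
  r <- readHeightMap(f)
  expect_lte(max(abs(heights(r) - heights(h))), 1 / (2^16 - 1))
})

test_that("multi-channel and non-finite inputs are rejected with named errors", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(4 * 4 * 3), c(4, 4, 3)), f)
  expect_error(readHeightMap(f), class = "ps_channel_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "NaN,3"), f2)
  err <- expect_error(readHeightMap(f2), class = "ps_validation_error")
  expect_match(conditionMessage(err), "\\[2, 1\\]")

  expect_error(readHeightMap(withr::local_tempfile(fileext = ".tif")),
               class = "ps_io_error")
})

test_that("normalization follows the min-max closed form", {
  h <- normalizeMap(HeightMap(matrix(c(0, 10, 5, 20), 2)))
  expect_equal(heights(h), matrix(c(0, 0.5, 0.25, 1), 2))
  expect_identical(normState(h), "unit_normalized")
  expect_equal(normParams(h), c(0, 20))
})

test_that("constant images normalize to zero with a recorded unit span", {
  h <- normalizeMap(HeightMap(matrix(3, 2, 2)))
  expect_equal(heights(h), matrix(0, 2, 2))
  expect_equal(normParams(h), c(3, 4))
  expect_equal(heights(denormalizeMap(h)), matrix(3, 2, 2))
})

test_that("normalize/denormalize round-trips and preserves pixel order", {
  set.seed(9)
  v <- matrix(rnorm(30 * 20, 2, 5), 30)
  h <- HeightMap(v, pixelSize = 0.12)
  hn <- normalizeMap(h)
  expect_true(all(heights(hn) >= 0 & heights(hn) <= 1))
  expect_identical(order(heights(hn)), order(v))  # monotone
  back <- denormalizeMap(hn)
  expect_lt(max(abs(heights(back) - v)) / max(abs(v)), 1e-9)
  expect_equal(pixelSize(back), 0.12)
  expect_error(normalizeMap(hn), class = "ps_state_error")
  expect_error(denormalizeMap(h), class = "ps_state_error")
})

test_that("line masks round-trip through PNG and CSV rasters", {
  lm <- randomLineMask(64, 0.25, seed = 4)
  for (ext in c(".png", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    writeLineMask(lm, f, n = 32)
    r <- readLineMask(f)
    expect_identical(maskKeep(r), maskKeep(lm))
  }
})

test_that("HeightMap validity rejects non-finite and out-of-range values", {
  expect_error(HeightMap(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(HeightMap(matrix(c(0, 0.5, 1, 2), 2),
                         normState = "unit_normalized", normParams = c(0, 1)),
               "must lie in")
})
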