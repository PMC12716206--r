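test_that("masked-line count is the exact rounded fraction with scanned borders", {
  for (gen in list(function() randomLineMask(256, 0.30, seed = 1),
                   function() randomLineMask(256, 0.30, maxConsecutive = 5, seed = 2),
                   function() patternedLineMask(256, 0.30, "fixed_distance"),
                   function() patternedLineMask(256, 0.30, "geometric"),
                   function() patternedLineMask(256, 0.30, "block"))) {
    lm <- gen()
    k <- maskKeep(lm)
    expect_identical(sum(!k), 77L)  # round(0.30 * 256) rounds half up to 77
    expect_true(k[1] && k[256])
  }
})

test_that("p = 0 yields the all-keep mask", {
  expect_true(all(maskKeep(randomLineMask(64, 0, seed = 1))))
  expect_true(all(maskKeep(patternedLineMask(64, 0, "fixed_distance"))))
})

test_that("run-limited random masks never exceed the consecutive-skip limit", {
  for (seed in 1:200) {
    lm <- randomLineMask(100, 0.3, maxConsecutive = 2, seed = seed)
    runs <- rle(maskKeep(lm))
    zero_runs <- runs$lengths[!runs$values]
    expect_lte(max(zero_runs), 2)
    expect_identical(sum(!maskKeep(lm)), 30L)
  }
})

test_that("fixed-distance skips are placed as evenly as brute force allows", {
  lm <- patternedLineMask(10, 0.2, "fixed_distance")
  skips <- which(!maskKeep(lm))
  gapSpread <- function(sk) {
    d <- diff(c(1, sk, 10))
    stats::var(d)
  }
  # brute force over all interior pairs
  cand <- utils::combn(2:9, 2)
  bestSpread <- min(apply(cand, 2, gapSpread))
  expect_equal(gapSpread(skips), bestSpread)
  expect_identical(length(skips), 2L)
})

test_that("block masks group skips into the requested contiguous runs", {
  lm <- patternedLineMask(256, 0.30, "block", blockLength = 77L)
  runs <- rle(maskKeep(lm))
  zero_runs <- runs$lengths[!runs$values]
  expect_identical(zero_runs, 77L)  # one contiguous run

  lm2 <- patternedLineMask(100, 0.2, "block", blockLength = 5L)
  runs2 <- rle(maskKeep(lm2))
  expect_true(all(runs2$lengths[!runs2$values] == 5L))
})

test_that("geometric masks have growing gaps between skipped lines", {
  lm <- patternedLineMask(200, 0.1, "geometric", ratio = 1.5)
  skips <- which(!maskKeep(lm))
  gaps <- diff(skips)
  expect_identical(length(skips), 20L)
  # gaps grow overall (monotone up to rounding)
  expect_gt(utils::tail(gaps, 1), utils::head(gaps, 1))
  expect_true(all(diff(gaps) >= -1))
})

test_that("infeasible masks raise infeasibility errors", {
  expect_error(randomLineMask(10, 0.95, seed = 1), class = "ps_infeasible_error")
  expect_error(randomLineMask(20, 0.6, maxConsecutive = 1, seed = 1),
               class = "ps_infeasible_error")
  expect_error(randomLineMask(3, 0.2, seed = 1), class = "ps_parameter_error")
})

test_that("expandMask broadcasts rows and preserves the masked fraction", {
  lm <- methods::new("LineMask", keep = c(TRUE, FALSE, TRUE), fraction = 1 / 3,
                     pattern = "manual", maxConsecutive = Inf, seed = NA_real_)
  mr <- expandMask(lm, 2)
  expect_equal(maskValues(mr), matrix(c(1, 0, 1, 1, 0, 1), 3, 2))
  expect_equal(mean(maskValues(mr) == 0), mean(!maskKeep(lm)))
  allk <- randomLineMask(16, 0, seed = 1)
  expect_true(all(maskValues(expandMask(allk, 5)) == 1))
})

test_that("random masks cover interior lines roughly uniformly", {
  counts <- integer(60)
  for (seed in 1:300) {
    lm <- randomLineMask(60, 0.3, seed = seed)
    counts <- counts + !maskKeep(lm)
  }
  interior <- counts[2:59]
  # every interior line is hit and no line dominates (sanity, not a strict gate)
  expect_true(all(interior > 0))
  expect_lt(max(interior) / mean(interior), 2)
  expect_identical(counts[1], 0L)
  expect_identical(counts[60], 0L)
})

test_that("scar extraction flags planted full-row scars and nothing else", {
  h <- generateScene(sceneParams(imageSize = c(96L, 96L),
                                 bodyRadiusRange = c(10, 30), seed = 21))
  out <- addScars(h, scarSpec(nScars = 2L, scarRows = c(10, 50),
                              scarOffsetRange = c(0.5, 1), seed = 3))
  sm <- extractScarMask(out$scarred)
  expect_identical(which(!maskKeep(sm)), c(10L, 50L))
})

test_that("clean and constant images produce all-keep scar masks", {
  h <- generateScene(sceneParams(imageSize = c(96L, 96L),
                                 bodyRadiusRange = c(10, 30), seed = 22))
  expect_true(all(maskKeep(extractScarMask(h))))
  expect_true(all(maskKeep(extractScarMask(HeightMap(matrix(2, 24, 24))))))
})
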