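test_that("linear interpolation recovers midpoints and linear ramps exactly", {
  v <- matrix(0, 3, 4)
  v[3, ] <- 2
  keep <- c(TRUE, FALSE, TRUE)
  lm <- methods::new("LineMask", keep = keep, fraction = 1 / 3,
                     pattern = "manual", maxConsecutive = Inf, seed = NA_real_)
  partial <- HeightMap(v)
  out <- interpolateLinear(partial, lm)
  expect_equal(heights(out)[2, ], rep(1, 4))

  # an image linear in the row index is recovered exactly under any mask
  ramp <- matrix(rep(seq(0, 1, length.out = 32), 16), 32, 16)
  lm2 <- randomLineMask(32, 0.4, seed = 2)
  acq <- acquirePartial(HeightMap(ramp, normState = "unit_normalized",
                                  normParams = c(0, 1)), lm2)
  rec <- interpolateLinear(acq$partial, acq$mask)
  expect_equal(heights(rec), ramp, tolerance = 1e-12)
})

test_that("interpolation with no holes is the identity", {
  h <- normalizeMap(smallScene(seed = 1))
  lm <- randomLineMask(48, 0, seed = 1)
  expect_identical(heights(interpolateLinear(h, lm)), heights(h))
})

test_that("interpolation requires scanned boundary rows", {
  h <- normalizeMap(smallScene(seed = 1))
  lm <- methods::new("LineMask", keep = c(FALSE, rep(TRUE, 47)),
                     fraction = 1 / 48, pattern = "manual",
                     maxConsecutive = Inf, seed = NA_real_)
  expect_error(interpolateLinear(h, lm), class = "ps_precondition_error")
})

test_that("median line correction replaces single scars with neighbour midpoints", {
  h <- smallScene(seed = 2)
  v <- heights(h)
  scar <- methods::new("LineMask", keep = replace(rep(TRUE, 48), 20, FALSE),
                       fraction = 1 / 48, pattern = "scar",
                       maxConsecutive = Inf, seed = NA_real_)
  out <- medianLineCorrect(h, scar)
  expect_equal(heights(out)[20, ], (v[19, ] + v[21, ]) / 2)
  expect_identical(heights(out)[-20, ], v[-20, ])
  # no flagged rows: identity
  clean <- methods::new("LineMask", keep = rep(TRUE, 48), fraction = 0,
                        pattern = "scar", maxConsecutive = Inf, seed = NA_real_)
  expect_identical(heights(medianLineCorrect(h, clean)), v)
})

test_that("adjacent scarred rows are corrected from the nearest clean rows", {
  v <- matrix(as.numeric(1:5), 5, 3)  # rows 1..5 constant per row
  v[3, ] <- 100
  v[4, ] <- -50
  scar <- methods::new("LineMask", keep = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                       fraction = 0.4, pattern = "scar",
                       maxConsecutive = Inf, seed = NA_real_)
  out <- medianLineCorrect(HeightMap(v), scar)
  # hand computation: nearest clean rows are 2 and 5 for both scarred rows
  expect_equal(heights(out)[3, ], rep((2 + 5) / 2, 3))
  expect_equal(heights(out)[4, ], rep((2 + 5) / 2, 3))

  # k = 2 uses the median of up to four clean rows
  out2 <- medianLineCorrect(HeightMap(v), scar, k = 2)
  expect_equal(heights(out2)[3, ], rep(stats::median(c(1, 2, 5)), 3))
})

test_that("correction fails only when no clean rows exist at all", {
  v <- matrix(1, 4, 3)
  allscar <- methods::new("LineMask", keep = rep(FALSE, 4), fraction = 1,
                          pattern = "scar", maxConsecutive = Inf,
                          seed = NA_real_)
  expect_error(medianLineCorrect(HeightMap(v), allscar),
               class = "ps_correction_error")
  # boundary scar with clean rows on one side only is handled one-sidedly
  edge <- methods::new("LineMask", keep = c(FALSE, TRUE, TRUE, TRUE),
                       fraction = 0.25, pattern = "scar",
                       maxConsecutive = Inf, seed = NA_real_)
  v[1, ] <- 99
  out <- medianLineCorrect(HeightMap(v), edge)
  expect_equal(heights(out)[1, ], v[2, ])
})
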