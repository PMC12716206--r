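# The desk-scale Partial-Scan study: generate a synthetic corpus, train the
# partial-convolution model and its plain-CNN ablation from scratch, compare
# them with linear interpolation on held-out scenes, sweep masking fractions
# for break-point regression, and run the scar detection/correction
# comparison. Both the acceptance script and the heavyweight tests drive this
# one entry point, so the studied conditions live in a single place.

#' Scene parameters of the desk-scale study corpus
#'
#' The 96 x 96 analogue of the default 256 x 256 scene: body radii scaled to
#' the frame, all other magnitudes identical.
#'
#' @param imageSize frame size (default c(96, 96)).
#' @return a \linkS4class{SceneParams}.
#' @export
studySceneParams <- function(imageSize = c(96L, 96L)) {
  sceneParams(imageSize = imageSize,
              bodyRadiusRange = c(20, 60) * min(imageSize) / 256)
}

#' Run the full Partial-Scan reconstruction study
#'
#' Trains a Partial-CNN and a plain CNN from scratch on synthetic SICM scenes
#' with per-epoch random line masks (30--35 % skipped), then evaluates both
#' against column-wise linear interpolation on held-out scenes at 30 %
#' masking, locates quality break-points across masking fractions, and
#' quantifies scar detection and correction. All randomness derives from
#' \code{seed}.
#'
#' @param seed master seed.
#' @param nTrain,nTest corpus split (defaults 200 / 20).
#' @param imageSize frame size (default c(96, 96)).
#' @param filters encoder ladder for the desk-scale models (default
#'   c(12, 24)).
#' @param epochs training epoch budget per model (default 45).
#' @param batchSize,learningRate optimizer settings for the desk-scale corpus
#'   (defaults 2 and 0.005 with plateau decay, Polyak averaging and random
#'   48-column training strips; see the methods vignette).
#' @param sweep run the masking-fraction sweep and break-point fits
#'   (default TRUE; the sweep reuses the trained Partial-CNN).
#' @param sweepFractions masking fractions for the break-point sweep.
#' @param sweepImages number of held-out scenes used per sweep point
#'   (default 6, for tractable sweeps).
#' @param sweepReplicates replicate masks per fraction (default 3).
#' @param nScarScenes scenes for the scar study (default 20).
#' @param verbose print training progress.
#' @return a list with elements \code{models} (partial, cnn),
#'   \code{comparison} (per-scene PSNR/SSIM for the three methods),
#'   \code{sweep} (\linkS4class{SweepResult}), \code{breakpoints} (per-metric
#'   \linkS4class{BreakpointFit}), and \code{scars} (sensitivity,
#'   false-positive rows per image, inpainting-vs-median win fraction).
#' @export
runStudy <- function(seed = 1L, nTrain = 200L, nTest = 20L,
                     imageSize = c(96L, 96L), filters = c(12L, 24L),
                     epochs = 45L, batchSize = 2L, learningRate = 0.005,
                     sweep = TRUE,
                     sweepFractions = seq(0.05, 0.90, by = 0.05),
                     sweepImages = 6L, sweepReplicates = 3L,
                     nScarScenes = 20L, verbose = FALSE) {
  sp <- studySceneParams(imageSize)
  raw <- generateDataset(nTrain + nTest, sp, seed = subSeed(seed, 1L))
  maps <- lapply(raw, normalizeMap)
  trainSet <- maps[seq_len(nTrain)]
  testSet <- maps[nTrain + seq_len(nTest)]

  tc <- trainConfig(batchSize = batchSize, learningRate = learningRate,
                    folds = 1L, maxEpochs = epochs, patience = 10L,
                    valFraction = 0.1, emaDecay = 0.995,
                    cropCols = min(48, imageSize[2L]),
                    seed = subSeed(seed, 2L))
  lc <- lossConfig()
  m <- imageSize[1L]

  cfgP <- modelConfig("partial_cnn", filters = filters, inputSize = imageSize)
  partial <- trainModel(buildModel(cfgP, seed = subSeed(seed, 3L)), trainSet,
                        tc, lc, verbose = verbose)
  cfgC <- modelConfig("cnn", filters = filters, inputSize = imageSize)
  cnn <- trainModel(buildModel(cfgC, seed = subSeed(seed, 3L)), trainSet,
                    tc, lc, verbose = verbose)

  # head-to-head on held-out scenes at 30 % masking
  comparison <- do.call(rbind, lapply(seq_along(testSet), function(i) {
    img <- testSet[[i]]
    lm <- randomLineMask(m, 0.30, seed = subSeed(seed, 100L + i))
    acq <- acquirePartial(img, lm)
    recP <- reconstruct(partial, acq$partial, acq$mask)
    recC <- reconstruct(cnn, acq$partial, acq$mask)
    recL <- interpolateLinear(acq$partial, acq$mask)
    data.frame(scene = i,
               psnr_partial = psnrMetric(img, recP),
               psnr_cnn = psnrMetric(img, recC),
               psnr_interp = psnrMetric(img, recL),
               ssim_partial = ssimMetric(img, recP),
               ssim_cnn = ssimMetric(img, recC),
               ssim_interp = ssimMetric(img, recL),
               mse_partial = mseMetric(img, recP),
               mse_cnn = mseMetric(img, recC),
               mse_interp = mseMetric(img, recL))
  }))

  sweepRes <- NULL
  breakpoints <- NULL
  if (sweep) {
    sweepRes <- maskingSweep(partial, testSet[seq_len(min(sweepImages, nTest))],
                             sweepFractions, replicates = sweepReplicates,
                             seed = subSeed(seed, 4L))
    tab <- sweepTable(sweepRes)
    breakpoints <- lapply(c(psnr = "psnr", ssim = "ssim"), function(mt) {
      sub <- tab[tab$metric == mt & is.finite(tab$mean), ]
      segmentedFit(sub$fraction, sub$mean)
    })
  }

  # scar study on freshly generated scenes
  scarRows <- lapply(seq_len(nScarScenes), function(i) {
    h <- generateScene(local({
      p <- sp
      p@seed <- as.numeric(subSeed(seed, 200L + i))
      p
    }))
    s <- scarSpec(nScars = 3L, scarOffsetRange = c(0.3, 1),
                  seed = subSeed(seed, 300L + i))
    planted <- addScars(h, s)
    truth <- !maskKeep(planted$mask)
    det <- extractScarMask(planted$scarred)
    detected <- !maskKeep(det)
    # correction comparison in the clean scene's normalized frame
    hn <- normalizeMap(h)
    span <- normParams(hn)
    scarredN <- HeightMap(
      pmin(pmax((heights(planted$scarred) - span[1L]) / diff(span), 0), 1),
      normState = "unit_normalized", normParams = span)
    corrMask <- det
    v <- heights(scarredN)
    v[!maskKeep(corrMask), ] <- 0
    partialIn <- HeightMap(v, normState = "unit_normalized", normParams = span)
    recI <- reconstruct(partial, partialIn, expandMask(corrMask, ncol(v)))
    recM <- medianLineCorrect(scarredN, corrMask)
    rows <- which(truth)
    mseOn <- function(rec) mean((heights(rec)[rows, ] - heights(hn)[rows, ])^2)
    data.frame(scene = i,
               nTrue = sum(truth),
               nDetected = sum(detected & truth),
               falsePos = sum(detected & !truth),
               mse_inpaint = mseOn(recI),
               mse_median = mseOn(recM))
  })
  scarTab <- do.call(rbind, scarRows)
  scars <- list(
    table = scarTab,
    sensitivity = sum(scarTab$nDetected) / sum(scarTab$nTrue),
    falsePositivesPerImage = mean(scarTab$falsePos),
    inpaintWinFraction = mean(scarTab$mse_inpaint < scarTab$mse_median))

  list(models = list(partial = partial, cnn = cnn),
       comparison = comparison, sweep = sweepRes, breakpoints = breakpoints,
       scars = scars,
       config = list(seed = seed, nTrain = nTrain, nTest = nTest,
                     imageSize = imageSize, filters = filters,
                     epochs = epochs))
}
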