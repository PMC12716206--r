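# The mask-aware encoder-decoder. Two architectures share one U-Net body of
# partial convolutions: "partial_cnn" takes the masked image plus its mask
# and propagates/updates the mask through every layer; "cnn" is the ablation
# that sees only the masked image (its internal mask is constantly all-valid,
# making every layer an ordinary renormalized convolution). Forward and
# backward passes are written directly against the layer primitives in
# nn-ops.R and verified by finite-difference tests.

#' Construct a model configuration
#'
#' @param arch \code{"partial_cnn"} (image + mask) or \code{"cnn"} (masked
#'   image only).
#' @param filters encoder filter ladder, one entry per pooling stage; the
#'   decoder mirrors it. Default is the full-scale four-stage ladder
#'   64/128/256/512; scaled-down studies use smaller ladders.
#' @param dropout bottleneck dropout rate (default 0.20).
#' @param kernel integer (kh, kw) convolution kernel (default c(5, 3): extra
#'   slow-axis context, matching the row geometry of line masks).
#' @param inputSize integer (rows, cols), divisible by 2^length(filters).
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(arch = c("partial_cnn", "cnn"),
                        filters = c(64L, 128L, 256L, 512L),
                        dropout = 0.20, kernel = c(5L, 3L),
                        inputSize = c(256L, 256L)) {
  arch <- match.arg(arch)
  methods::new("ModelConfig", arch = arch, filters = as.integer(filters),
               dropout = as.numeric(dropout), kernel = as.integer(kernel),
               inputSize = as.integer(inputSize))
}

#' Construct a loss configuration
#'
#' @param alpha structural-term weight in [0, 1] (default 0.96).
#' @param ssimWindow odd SSIM window (default 7).
#' @return a \linkS4class{LossConfig}.
#' @export
lossConfig <- function(alpha = 0.96, ssimWindow = 7L) {
  methods::new("LossConfig", alpha = as.numeric(alpha),
               ssimWindow = as.integer(ssimWindow))
}

#' Construct a training configuration
#'
#' @param batchSize minibatch size (default 16).
#' @param learningRate Adam step size (default 0.0005).
#' @param folds cross-validation folds (default 3; 1 = plain split).
#' @param valFraction validation fraction when folds = 1 (default 0.2).
#' @param maxEpochs epoch budget (default 200).
#' @param patience early-stopping patience on validation loss (default 10).
#' @param pRange training mask fraction range (default c(0.30, 0.35)).
#' @param lrDecay learning-rate factor applied when validation loss stalls
#'   for half the patience (default 0.5; 1 disables the schedule).
#' @param warmupEpochs linear learning-rate warmup over the first epochs
#'   (default 3; guards Adam against early bad basins).
#' @param clipNorm global gradient-norm clip (default 5; Inf disables).
#' @param emaDecay Polyak weight-averaging decay per optimizer step; the
#'   averaged weights are validated and returned (default 0 = off).
#' @param cropCols width of random vertical training strips (default NA =
#'   full frames). Strips keep every scan line, so the line-mask geometry is
#'   unchanged; the fitted network stays fully convolutional and evaluates
#'   on full frames.
#' @param seed RNG seed controlling initialization, splits and masks.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(batchSize = 16L, learningRate = 5e-4, folds = 3L,
                        valFraction = 0.2, maxEpochs = 200L, patience = 10L,
                        pRange = c(0.30, 0.35), lrDecay = 0.5, emaDecay = 0,
                        cropCols = NA_real_, warmupEpochs = 3L, clipNorm = 5,
                        seed = 1L) {
  methods::new("TrainConfig", batchSize = as.integer(batchSize),
               learningRate = as.numeric(learningRate),
               folds = as.integer(folds), valFraction = as.numeric(valFraction),
               maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
               pRange = as.numeric(pRange), lrDecay = as.numeric(lrDecay),
               emaDecay = as.numeric(emaDecay), cropCols = as.numeric(cropCols),
               warmupEpochs = as.integer(warmupEpochs),
               clipNorm = as.numeric(clipNorm), seed = as.numeric(seed))
}

# weight shapes for a config: encoder ladder, bottleneck, mirrored decoder
# with skip concatenation, output head. The tall (kh x kw) kernel is used
# where the raw line-mask geometry lives -- the first encoder layer and the
# head, both at full resolution -- while pooled-scale layers (where a
# skipped-line run has shrunk) use 3x3, which also keeps the wide decoder
# layers affordable.
.layerPlan <- function(cfg) {
  f <- cfg@filters
  D <- length(f)
  inner <- c(3L, 3L)
  enc <- list()
  encK <- list()
  cin <- 1L
  for (kk in seq_len(D)) {
    enc[[kk]] <- c(cin, f[kk])
    encK[[kk]] <- if (kk == 1L) cfg@kernel else inner
    cin <- f[kk]
  }
  bot <- c(f[D], 2L * f[D])
  dec <- list()
  prev <- 2L * f[D]
  for (kk in rev(seq_len(D))) {
    dec[[kk]] <- c(prev + f[kk], f[kk])
    prev <- f[kk]
  }
  # the output head also sees the (masked) input image itself, so copying
  # acquired lines through is cheap to learn and capacity goes to the holes
  list(enc = enc, encK = encK, bot = bot, botK = inner, dec = dec,
       decK = rep(list(inner), D), out = c(f[1L] + 1L, 1L),
       outK = cfg@kernel, depth = D)
}

.initLayer <- function(cin, cout, K) {
  # He initialization for ReLU layers
  list(W = matrix(stats::rnorm(K * cin * cout, 0, sqrt(2 / (K * cin))),
                  K * cin, cout),
       b = rep(0, cout))
}

#' Build an (untrained) inpainting model
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param seed RNG seed for weight initialization.
#' @return an \linkS4class{InpaintingModel}.
#' @examples
#' m <- buildModel(modelConfig(filters = c(8L, 16L), inputSize = c(64L, 64L)))
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopifnot(methods::is(cfg, "ModelConfig"))
  plan <- .layerPlan(cfg)
  Kout <- prod(plan$outK)
  weights <- withSeed(seed, {
    w <- list(enc = Map(function(s, k) .initLayer(s[1L], s[2L], prod(k)),
                        plan$enc, plan$encK),
              bot = .initLayer(plan$bot[1L], plan$bot[2L], prod(plan$botK)),
              dec = Map(function(s, k) .initLayer(s[1L], s[2L], prod(k)),
                        plan$dec, plan$decK),
              out = .initLayer(plan$out[1L], plan$out[2L], Kout))
    # residual-style head initialization: the output starts as the identity
    # on the (masked) input channel, so training spends its budget on the
    # skipped lines rather than on re-learning the copy-through
    w$out$W[] <- 0
    w$out$W[Kout * cfg@filters[1L] + (Kout + 1L) %/% 2L, 1L] <- 1
    w
  })
  methods::new("InpaintingModel", config = cfg, weights = weights,
               history = data.frame(), trained = FALSE)
}

#' Number of trainable parameters of a model
#' @param model an \linkS4class{InpaintingModel}.
#' @return integer count.
#' @export
nParameters <- function(model) {
  flat <- unlist(model@weights, recursive = TRUE, use.names = FALSE)
  length(flat)
}

# forward pass; x and mask are H x W matrices; returns prediction and the
# caches needed for backprop
.forward <- function(weights, cfg, x, mask, training = FALSE) {
  D <- length(cfg@filters)
  plan <- .layerPlan(cfg)
  if (cfg@arch == "cnn") mask <- matrix(1, nrow(x), ncol(x))
  feat <- array(x, c(nrow(x), ncol(x), 1L))
  m <- mask
  skipFeat <- vector("list", D)
  skipMask <- vector("list", D)
  encC <- vector("list", D)
  for (kk in seq_len(D)) {
    pc <- .pconvForward(feat, m, weights$enc[[kk]]$W, weights$enc[[kk]]$b, plan$encK[[kk]])
    act <- .relu(pc$out)
    skipFeat[[kk]] <- act
    skipMask[[kk]] <- pc$newMask
    pl <- .poolForward(act)
    encC[[kk]] <- list(pconv = pc$cache, pre = pc$out, pool = pl)
    feat <- pl$out
    m <- .poolMask(pc$newMask)
  }
  pcB <- .pconvForward(feat, m, weights$bot$W, weights$bot$b, plan$botK)
  actB <- .relu(pcB$out)
  dr <- .dropoutForward(actB, if (training) cfg@dropout else 0)
  feat <- dr$out
  m <- pcB$newMask
  decC <- vector("list", D)
  for (kk in rev(seq_len(D))) {
    up <- .upsampleForward(feat)
    mUp <- .upsampleMask(m)
    cat_ <- .concatChannels(up, skipFeat[[kk]])
    pc <- .pconvForward2(cat_, mUp, dim(up)[3L], skipMask[[kk]],
                         weights$dec[[kk]]$W, weights$dec[[kk]]$b,
                         plan$decK[[kk]])
    act <- .relu(pc$out)
    decC[[kk]] <- list(pconv = pc$cache, pre = pc$out,
                       upChannels = dim(up)[3L])
    feat <- act
    m <- pc$newMask
  }
  # the head sees the decoder features plus the raw masked input channel,
  # each with its own validity mask
  featO <- .concatChannels(feat, array(x, c(nrow(x), ncol(x), 1L)))
  pcO <- .pconvForward2(featO, m, dim(feat)[3L], mask,
                        weights$out$W, weights$out$b, plan$outK)
  pred <- pcO$out[, , 1L]  # linear head; clipped to [0, 1] at reconstruction
  list(pred = pred,
       cache = list(encC = encC, skip = skipFeat,
                    botC = list(pconv = pcB$cache, pre = pcB$out,
                                dropMask = dr$mask),
                    decC = decC, outC = list(pconv = pcO$cache, pred = pred)))
}

# backward pass; dPred is dLoss/dPrediction (H x W). Returns gradients with
# the same structure as the weights list.
.backward <- function(weights, cfg, cache, dPred) {
  D <- length(cfg@filters)
  g <- list(enc = vector("list", D), bot = NULL, dec = vector("list", D),
            out = NULL)
  dz <- array(dPred, c(dim(dPred), 1L))
  bo <- .pconvBackward2(dz, cache$outC$pconv, weights$out$W)
  g$out <- list(W = bo$dW, b = bo$db)
  # drop the gradient slice of the concatenated raw-input channel
  dFeat <- bo$dx[, , seq_len(dim(bo$dx)[3L] - 1L), drop = FALSE]
  dSkip <- vector("list", D)
  for (kk in seq_len(D)) {
    dAct <- .reluBackward(dFeat, cache$decC[[kk]]$pre)
    bd <- .pconvBackward2(dAct, cache$decC[[kk]]$pconv, weights$dec[[kk]]$W)
    g$dec[[kk]] <- list(W = bd$dW, b = bd$db)
    nUp <- cache$decC[[kk]]$upChannels
    dUp <- bd$dx[, , seq_len(nUp), drop = FALSE]
    dSkip[[kk]] <- bd$dx[, , nUp + seq_len(dim(bd$dx)[3L] - nUp), drop = FALSE]
    dFeat <- .upsampleBackward(dUp)
  }
  if (!is.null(cache$botC$dropMask)) dFeat <- dFeat * cache$botC$dropMask
  dActB <- .reluBackward(dFeat, cache$botC$pre)
  bb <- .pconvBackward(dActB, cache$botC$pconv, weights$bot$W)
  g$bot <- list(W = bb$dW, b = bb$db)
  dFeat <- bb$dx
  for (kk in rev(seq_len(D))) {
    dPool <- .poolBackward(dFeat, cache$encC[[kk]]$pool)
    dAct <- dPool + dSkip[[kk]]
    dAct <- .reluBackward(dAct, cache$encC[[kk]]$pre)
    be <- .pconvBackward(dAct, cache$encC[[kk]]$pconv, weights$enc[[kk]]$W)
    g$enc[[kk]] <- list(W = be$dW, b = be$db)
    dFeat <- be$dx
  }
  g
}

#' Combined structural + pixel loss
#'
#' \code{alpha * (1 - meanSSIM(yTrue, yPred)) + (1 - alpha) * MSE(yTrue, yPred)}.
#' Zero if and only if the images agree (up to SSIM's stabilising constants).
#'
#' @param yTrue,yPred unit-normalized \linkS4class{HeightMap}s or matrices of
#'   equal size.
#' @param lc a \linkS4class{LossConfig}.
#' @return non-negative scalar.
#' @examples
#' a <- matrix(runif(64 * 64), 64)
#' combinedLoss(a, a)  # 0
#' @export
combinedLoss <- function(yTrue, yPred, lc = lossConfig()) {
  a <- if (methods::is(yTrue, "HeightMap")) yTrue@values else as.matrix(yTrue)
  b <- if (methods::is(yPred, "HeightMap")) yPred@values else as.matrix(yPred)
  if (!all(dim(a) == dim(b)))
    psStop("ps_dimension_error", "images must have equal dimensions")
  lssim <- 1 - ssimCore(a, b, lc@ssimWindow)
  lmse <- mean((a - b)^2)
  lc@alpha * lssim + (1 - lc@alpha) * lmse
}

# gradient of the combined loss with respect to yPred
.combinedLossGrad <- function(yTrue, yPred, lc) {
  lc@alpha * (-ssimGradCore(yTrue, yPred, lc@ssimWindow)) +
    (1 - lc@alpha) * 2 * (yPred - yTrue) / length(yTrue)
}

# loss value and gradient from one pass of SSIM window statistics
.combinedLossValGrad <- function(yTrue, yPred, lc) {
  sg <- ssimValGradCore(yTrue, yPred, lc@ssimWindow)
  list(loss = lc@alpha * (1 - sg$mssim) + (1 - lc@alpha) * mean((yTrue - yPred)^2),
       grad = lc@alpha * (-sg$grad) +
         (1 - lc@alpha) * 2 * (yPred - yTrue) / length(yTrue))
}

# Adam optimizer over the nested weights list
.adamInit <- function(weights) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  list(m = zero(weights), v = zero(weights), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, gv, mv, vv) {
    if (is.list(w)) {
      out <- list(w = w, m = mv, v = vv)
      for (nm in seq_along(w)) {
        r <- upd(w[[nm]], gv[[nm]], mv[[nm]], vv[[nm]])
        out$w[[nm]] <- r$w
        out$m[[nm]] <- r$m
        out$v[[nm]] <- r$v
      }
      out
    } else {
      m2 <- beta1 * mv + (1 - beta1) * gv
      v2 <- beta2 * vv + (1 - beta2) * gv^2
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(w = w - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  r <- upd(weights, grads, state$m, state$v)
  list(weights = r$w, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two nested gradient lists
.gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- .gradAdd(a[[nm]], b[[nm]])
    out
  } else a + b
}

.gradScale <- function(a, s) {
  if (is.list(a)) lapply(a, .gradScale, s = s) else a * s
}

.asMatrixList <- function(images) {
  lapply(images, function(im) {
    if (methods::is(im, "HeightMap")) {
      if (im@normState != "unit_normalized")
        psStop("ps_state_error", "training images must be unit-normalized")
      im@values
    } else as.matrix(im)
  })
}

#' Train an inpainting model on full images with on-the-fly line masking
#'
#' Every epoch draws a fresh random line mask per training image with masked
#' fraction sampled uniformly from \code{pRange} (mask augmentation), zeroes
#' the skipped rows, and optimizes the combined SSIM + MSE loss between the
#' network output and the full image with Adam. With \code{folds > 1} the
#' images are partitioned into folds, each fold serving once as the
#' validation set; the returned weights are those with the best validation
#' loss seen in any fold, and the history records every fold. Validation
#' masks are fixed per fold so early stopping compares like with like. Fully
#' reproducible for a fixed \code{tc@seed}.
#'
#' @param model an \linkS4class{InpaintingModel} from [buildModel()] (its
#'   weights are used as the initialization of every fold's run).
#' @param images list of unit-normalized \linkS4class{HeightMap}s (or
#'   matrices) of identical size matching the model input size.
#' @param tc a \linkS4class{TrainConfig}.
#' @param lc a \linkS4class{LossConfig}.
#' @param maskSampler optional function(m, seed) returning a
#'   \linkS4class{LineMask}; defaults to [randomLineMask()] with p drawn from
#'   \code{tc@pRange}.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{InpaintingModel} with history.
#' @export
trainModel <- function(model, images, tc = trainConfig(), lc = lossConfig(),
                       maskSampler = NULL, verbose = FALSE) {
  stopifnot(methods::is(model, "InpaintingModel"))
  if (length(images) == 0L) psStop("ps_data_error", "empty training set")
  mats <- .asMatrixList(images)
  dims <- vapply(mats, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    psStop("ps_dimension_error", "training images must share one shape")
  if (any(dims[, 1L] != model@config@inputSize))
    psStop("ps_dimension_error", "image size does not match model inputSize")
  cfg <- model@config
  nImg <- length(mats)
  m <- nrow(mats[[1L]])

  sampleMask <- function(seed) {
    if (!is.null(maskSampler)) return(maskSampler(m, seed))
    p <- withSeed(seed, stats::runif(1L, tc@pRange[1L], tc@pRange[2L]))
    randomLineMask(m, p, seed = seed + 1L)
  }
  maskedInput <- function(img, lm) {
    x <- img
    x[!lm@keep, ] <- 0
    list(x = x, mr = matrix(as.numeric(lm@keep), m, ncol(img)))
  }

  best <- list(loss = Inf, weights = model@weights)
  history <- list()

  withSeed(tc@seed, {
    foldOf <- if (tc@folds > 1L) {
      sample(rep(seq_len(tc@folds), length.out = nImg))
    } else {
      nVal <- max(1L, roundHalfUp(tc@valFraction * nImg))
      f <- rep(2L, nImg)
      f[sample(nImg, nVal)] <- 1L
      f
    }
    nFolds <- if (tc@folds > 1L) tc@folds else 1L
    maskSeedBase <- floor(stats::runif(1L) * 1e6)

    for (fold in seq_len(nFolds)) {
      valIdx <- which(foldOf == fold)
      trIdx <- setdiff(seq_len(nImg), valIdx)
      if (length(trIdx) == 0L) psStop("ps_data_error", "no training images in fold")
      weights <- model@weights
      ema <- weights
      useEma <- tc@emaDecay > 0
      adam <- .adamInit(weights)
      valMasks <- lapply(seq_along(valIdx), function(i)
        sampleMask(subSeed(maskSeedBase, fold * 10000L + i)))
      bad <- 0L
      stall <- 0L
      bestFold <- Inf
      baseLr <- tc@learningRate
      for (epoch in seq_len(tc@maxEpochs)) {
        lr <- if (tc@warmupEpochs > 0L && epoch <= tc@warmupEpochs)
          baseLr * epoch / (tc@warmupEpochs + 1L) else baseLr
        ord <- sample(trIdx)
        losses <- numeric(0L)
        batchGrad <- NULL
        batchLoss <- 0
        inBatch <- 0L
        for (ii in seq_along(ord)) {
          lm <- sampleMask(subSeed(maskSeedBase,
                                   fold * 1000000L + epoch * 1000L + ii))
          target <- mats[[ord[ii]]]
          if (!is.na(tc@cropCols) && tc@cropCols < ncol(target)) {
            j0 <- sample(ncol(target) - tc@cropCols + 1L, 1L)
            target <- target[, j0:(j0 + tc@cropCols - 1L), drop = FALSE]
          }
          mi <- maskedInput(target, lm)
          fw <- .forward(weights, cfg, mi$x, mi$mr, training = TRUE)
          lg <- .combinedLossValGrad(target, fw$pred, lc)
          loss <- lg$loss
          gr <- .backward(weights, cfg, fw$cache, lg$grad)
          batchGrad <- .gradAdd(batchGrad, gr)
          batchLoss <- batchLoss + loss
          inBatch <- inBatch + 1L
          if (inBatch == tc@batchSize || ii == length(ord)) {
            g <- .gradScale(batchGrad, 1 / inBatch)
            if (is.finite(tc@clipNorm)) {
              gn <- sqrt(sum(unlist(g, use.names = FALSE)^2))
              if (gn > tc@clipNorm) g <- .gradScale(g, tc@clipNorm / gn)
            }
            st <- .adamStep(weights, g, adam, lr)
            weights <- st$weights
            adam <- st$state
            if (useEma) {
              d <- tc@emaDecay
              mix <- function(a, b) {
                if (is.list(a)) Map(mix, a, b) else d * a + (1 - d) * b
              }
              ema <- mix(ema, weights)
            }
            losses <- c(losses, batchLoss / inBatch)
            batchGrad <- NULL
            batchLoss <- 0
            inBatch <- 0L
          }
        }
        evalWeights <- if (useEma) ema else weights
        valLoss <- mean(vapply(seq_along(valIdx), function(i) {
          mi <- maskedInput(mats[[valIdx[i]]], valMasks[[i]])
          fw <- .forward(evalWeights, cfg, mi$x, mi$mr, training = FALSE)
          combinedLoss(mats[[valIdx[i]]], fw$pred, lc)
        }, numeric(1L)))
        trLoss <- mean(losses)
        history[[length(history) + 1L]] <-
          data.frame(fold = fold, epoch = epoch, train_loss = trLoss,
                     val_loss = valLoss)
        if (verbose)
          message(sprintf("fold %d epoch %3d lr %.2g train %.5f val %.5f",
                          fold, epoch, lr, trLoss, valLoss))
        if (valLoss < bestFold - 1e-7) {
          bestFold <- valLoss
          bad <- 0L
          stall <- 0L
        } else {
          bad <- bad + 1L
          stall <- stall + 1L
          if (tc@lrDecay < 1 && stall >= max(1L, tc@patience %/% 2L)) {
            baseLr <- baseLr * tc@lrDecay
            stall <- 0L
          }
        }
        if (valLoss < best$loss) {
          best$loss <- valLoss
          best$weights <- evalWeights
        }
        if (bad >= tc@patience) break
      }
    }
  })
  methods::new("InpaintingModel", config = cfg, weights = best$weights,
               history = do.call(rbind, history), trained = TRUE)
}

#' @rdname reconstruct
#' @export
setMethod("reconstruct", signature("InpaintingModel", "HeightMap", "MaskRaster"),
  function(model, partial, mask, composite = TRUE, symmetrize = TRUE) {
    x <- partial@values
    mr <- mask@values
    if (!all(dim(x) == dim(mr)))
      psStop("ps_dimension_error", "partial image and mask must be congruent")
    if (!all(dim(x) == model@config@inputSize))
      psStop("ps_dimension_error", "input size does not match model config")
    fwd <- function(xx, mm) .forward(model@weights, model@config, xx, mm)$pred
    out <- fwd(x, mr)
    if (symmetrize) {
      ri <- rev(seq_len(nrow(x)))
      ci <- rev(seq_len(ncol(x)))
      out <- (out +
        fwd(x[, ci], mr[, ci])[, ci] +
        fwd(x[ri, ], mr[ri, ])[ri, ] +
        fwd(x[ri, ci], mr[ri, ci])[ri, ci]) / 4
    }
    if (composite) out <- mr * x + (1 - mr) * out
    out <- pmin(pmax(out, 0), 1)
    HeightMap(out, pixelSize = partial@pixelSize,
              normState = "unit_normalized", normParams = partial@normParams)
  })

#' @rdname reconstruct
#' @export
setMethod("reconstruct", signature("InpaintingModel", "HeightMap", "LineMask"),
  function(model, partial, mask, composite = TRUE, symmetrize = TRUE) {
    reconstruct(model, partial, expandMask(mask, ncol(partial@values)),
                composite = composite, symmetrize = symmetrize)
  })

#' Save / load a model
#'
#' The checkpoint is R's native serialization of the model object plus a
#' plain-text JSON sidecar describing the architecture.
#'
#' @param model an \linkS4class{InpaintingModel}.
#' @param path checkpoint path (.rds).
#' @return \code{writeModel}: the path, invisibly. \code{readModel}: the
#'   model.
#' @export
writeModel <- function(model, path) {
  saveRDS(model, path)
  cfg <- model@config
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(arch = cfg@arch, filters = cfg@filters,
                            dropout = cfg@dropout, inputSize = cfg@inputSize,
                            trained = model@trained,
                            nParameters = nParameters(model)),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  model <- readRDS(path)
  if (!methods::is(model, "InpaintingModel"))
    psStop("ps_format_error", "file does not contain an InpaintingModel")
  model
}
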