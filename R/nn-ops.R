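# Low-level layer operations of the encoder-decoder: partial 3x3
# convolution (forward and backward), 2x2 max pooling, nearest-neighbour
# upsampling, channel concatenation, dropout and the sigmoid output. Feature
# maps are (H, W, C) arrays; the validity mask is a single (H, W) 0/1 matrix
# shared across channels. Convolutions use im2col + BLAS matmul with cached
# window indices.

.idxCache <- new.env(parent = emptyenv())

# im2col linear indices: (H*W) x k^2 matrix of positions into the zero-padded
# (H+2p) x (W+2p) grid, column-major, slot order (dr fastest, then dc)
.convIdx <- function(H, W, k = 3L) {
  key <- paste(H, W, k, sep = "_")
  cached <- .idxCache[[key]]
  if (!is.null(cached)) return(cached)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  pos_i <- rep(seq_len(H), W)
  pos_j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k)
  s <- 1L
  for (dc in seq_len(k)) {
    for (dr in seq_len(k)) {
      idx[, s] <- (pos_i + dr - 1L) + (pos_j + dc - 2L) * Hp
      s <- s + 1L
    }
  }
  .idxCache[[key]] <- idx
  idx
}

# x: (H, W, Cin); returns (H*W) x (k^2 * Cin), columns ordered slot-fastest
.im2col <- function(xpad, idx, HW, k2) {
  xp2 <- matrix(xpad, nrow = dim(xpad)[1L] * dim(xpad)[2L])
  A <- xp2[as.vector(idx), , drop = FALSE]
  dim(A) <- c(HW, k2 * ncol(xp2))
  A
}

#' Partial convolution of a single window (reference contract)
#'
#' The scalar primitive of mask-aware convolution: with at least one valid
#' pixel in the window the output is the masked dot product rescaled by
#' window size over valid count, plus bias, and the updated mask bit is 1;
#' with no valid pixel the output is 0 and the mask bit 0.
#'
#' @param windowValues numeric patch (k x k).
#' @param windowMask binary patch of the same shape (1 = valid).
#' @param kernel numeric k x k kernel.
#' @param bias scalar bias.
#' @return list with \code{value} and \code{maskBit}.
#' @examples
#' partialConv(matrix(1, 3, 3), matrix(1, 3, 3), matrix(1/9, 3, 3), 0)
#' @export
partialConv <- function(windowValues, windowMask, kernel, bias = 0) {
  if (!all(dim(windowValues) == dim(windowMask)) ||
      !all(dim(windowValues) == dim(kernel)))
    psStop("ps_dimension_error", "window, mask and kernel must be congruent")
  s <- sum(windowMask)
  if (s > 0) {
    list(value = sum(kernel * (windowValues * windowMask)) *
           (length(windowMask) / s) + bias,
         maskBit = 1)
  } else {
    list(value = 0, maskBit = 0)
  }
}

# full partial-convolution layer, 3x3, stride 1, zero padding (padding is
# invalid: the mask is zero-padded too, so border windows renormalize).
# Production path is the compiled kernel; .pconvForwardR/.pconvBackwardR are
# the pure-R reference implementation kept as the independent oracle for the
# compiled code.
# compute precision: float32 (the default, as in mainstream deep-learning
# practice; roughly doubles matmul throughput) or float64 via
# options(PartialScan.doublePrecision = TRUE). The two paths are
# cross-checked in the tests; gradient finite-difference checks use the
# double path.
.useDouble <- function() isTRUE(getOption("PartialScan.doublePrecision"))

.pconvForward <- function(x, mask, W, b, kernel = c(3L, 3L)) {
  r <- if (.useDouble()) {
    .pconvForwardCpp(x, mask, W, b, kernel[1L], kernel[2L])
  } else {
    .pconvForwardCppF(x, mask, W, b, kernel[1L], kernel[2L])
  }
  list(out = r$out, newMask = r$newMask,
       cache = list(x = x, mask = mask, kernel = kernel))
}

.pconvBackward <- function(dOut, cache, W) {
  r <- if (.useDouble()) {
    .pconvBackwardCpp(dOut, cache$x, cache$mask, W,
                      cache$kernel[1L], cache$kernel[2L])
  } else {
    .pconvBackwardCppF(dOut, cache$x, cache$mask, W,
                       cache$kernel[1L], cache$kernel[2L])
  }
  r$db <- as.numeric(r$db)
  r
}

# two-group variant used at skip concatenations: the first n1 channels carry
# mask1, the rest mask2 (per-group validity, as in the reference design)
.pconvForward2 <- function(x, mask1, n1, mask2, W, b, kernel = c(3L, 3L)) {
  r <- if (.useDouble()) {
    .pconvForward2Cpp(x, mask1, n1, mask2, W, b, kernel[1L], kernel[2L])
  } else {
    .pconvForward2CppF(x, mask1, n1, mask2, W, b, kernel[1L], kernel[2L])
  }
  list(out = r$out, newMask = r$newMask,
       cache = list(x = x, mask1 = mask1, n1 = n1, mask2 = mask2,
                    kernel = kernel, twoGroup = TRUE))
}

.pconvBackward2 <- function(dOut, cache, W) {
  r <- if (.useDouble()) {
    .pconvBackward2Cpp(dOut, cache$x, cache$mask1, cache$n1, cache$mask2, W,
                       cache$kernel[1L], cache$kernel[2L])
  } else {
    .pconvBackward2CppF(dOut, cache$x, cache$mask1, cache$n1, cache$mask2, W,
                        cache$kernel[1L], cache$kernel[2L])
  }
  r$db <- as.numeric(r$db)
  r
}

.pconvForwardR <- function(x, mask, W, b, k = 3L) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  p <- (k - 1L) %/% 2L
  idx <- .convIdx(H, Wd, k)
  HW <- H * Wd
  k2 <- k * k
  mpad <- padMatrix(mask, p)
  Mcol <- matrix(mpad[as.vector(idx)], HW, k2)
  cnt <- rowSums(Mcol)
  valid <- as.numeric(cnt > 0)
  scale <- ifelse(cnt > 0, k2 / cnt, 0)
  xm <- x * as.vector(mask)        # broadcast over channels
  X <- .im2col(padArray(xm, p), idx, HW, k2)
  Y <- X %*% W
  Y <- Y * scale
  Y <- Y + outer(valid, b)
  out <- array(Y, c(H, Wd, ncol(W)))
  list(out = out,
       newMask = matrix(valid, H, Wd),
       cache = list(X = X, scale = scale, valid = valid, mask = mask,
                    dims = c(H, Wd, Cin), k = k))
}

.pconvBackwardR <- function(dOut, cache, W) {
  H <- cache$dims[1L]; Wd <- cache$dims[2L]; Cin <- cache$dims[3L]
  k <- cache$k
  k2 <- k * k
  p <- (k - 1L) %/% 2L
  HW <- H * Wd
  idx <- .convIdx(H, Wd, k)
  dY <- matrix(dOut, HW, dim(dOut)[3L])
  dY <- dY * cache$valid
  db <- colSums(dY)
  dYs <- dY * cache$scale
  dW <- crossprod(cache$X, dYs)
  dXcol <- tcrossprod(dYs, W)      # HW x (k2 * Cin)
  Hp <- H + 2L * p
  Wp <- Wd + 2L * p
  dxp2 <- matrix(0, Hp * Wp, Cin)
  for (s in seq_len(k2)) {
    cols <- s + k2 * (seq_len(Cin) - 1L)
    dxp2[idx[, s], ] <- dxp2[idx[, s], ] + dXcol[, cols, drop = FALSE]
  }
  dxp <- array(dxp2, c(Hp, Wp, Cin))
  dx <- dxp[(p + 1L):(p + H), (p + 1L):(p + Wd), , drop = FALSE]
  dx <- dx * as.vector(cache$mask)
  list(dx = dx, dW = dW, db = db)
}

.relu <- function(x) .reluCpp(x)

.reluBackward <- function(dOut, preact) .reluBackwardCpp(dOut, preact)

# 2x2 max pooling, stride 2; ties break toward the earlier slot
.poolForward <- function(x) {
  r <- .poolForwardCpp(x)
  list(out = r$out, choice = r$choice, inDim = dim(x))
}

.poolBackward <- function(dOut, cache) {
  .poolBackwardCpp(dOut, cache$choice, cache$inDim[1L], cache$inDim[2L])
}

.upsampleForward <- function(x) .upsampleForwardCpp(x)

.upsampleBackward <- function(dOut) .upsampleBackwardCpp(dOut)

# pure-R reference implementations (oracles for the compiled kernels)
.poolForwardR <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  s1 <- x[ro, co, , drop = FALSE]; s2 <- x[re, co, , drop = FALSE]
  s3 <- x[ro, ce, , drop = FALSE]; s4 <- x[re, ce, , drop = FALSE]
  v12 <- pmax(s1, s2); c12 <- ifelse(s1 >= s2, 1L, 2L)
  v34 <- pmax(s3, s4); c34 <- ifelse(s3 >= s4, 3L, 4L)
  out <- pmax(v12, v34)
  choice <- ifelse(v12 >= v34, c12, c34)
  list(out = out, choice = choice, inDim = d)
}

.poolBackwardR <- function(dOut, cache) {
  d <- cache$inDim
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  slots <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (kk in 1:4) {
    tmp <- array(0, dim(dOut))
    sel <- cache$choice == kk
    tmp[sel] <- dOut[sel]
    dx[slots[[kk]][[1L]], slots[[kk]][[2L]], ] <-
      dx[slots[[kk]][[1L]], slots[[kk]][[2L]], , drop = FALSE] + tmp
  }
  dx
}

# mask pooling: pooled bit is 1 if any contributing bit is 1
.poolMask <- function(m) {
  ro <- seq(1L, nrow(m), 2L); re <- seq(2L, nrow(m), 2L)
  co <- seq(1L, ncol(m), 2L); ce <- seq(2L, ncol(m), 2L)
  pmax(m[ro, co, drop = FALSE], m[re, co, drop = FALSE],
       m[ro, ce, drop = FALSE], m[re, ce, drop = FALSE])
}

.upsampleForwardR <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

.upsampleBackwardR <- function(dOut) {
  d <- dim(dOut)
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  dOut[ro, co, , drop = FALSE] + dOut[re, co, , drop = FALSE] +
    dOut[ro, ce, , drop = FALSE] + dOut[re, ce, , drop = FALSE]
}

.upsampleMask <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L),
    drop = FALSE]
}

.concatChannels <- function(a, b) .concatChannelsCpp(a, b)

# inverted dropout; mask sampled from the current RNG stream
.dropoutForward <- function(x, rate) {
  if (rate <= 0) return(list(out = x, mask = NULL))
  keep <- array(stats::rbinom(length(x), 1L, 1 - rate), dim(x)) / (1 - rate)
  list(out = x * keep, mask = keep)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
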