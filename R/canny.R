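# Canny edge detection: Gaussian smoothing, Sobel gradients, 4-direction
# non-maximum suppression and hysteresis linking. Written against plain
# matrices; no installed R package provides a Canny implementation.

.sobel <- function(x) {
  xp <- padReplicate(x, 1L)
  h <- nrow(x); w <- ncol(x)
  i <- 2:(h + 1L); j <- 2:(w + 1L)
  # Sobel kernels; gx = horizontal derivative (columns), gy = vertical (rows)
  gx <- (xp[i - 1L, j + 1L] + 2 * xp[i, j + 1L] + xp[i + 1L, j + 1L]) -
        (xp[i - 1L, j - 1L] + 2 * xp[i, j - 1L] + xp[i + 1L, j - 1L])
  gy <- (xp[i + 1L, j - 1L] + 2 * xp[i + 1L, j] + xp[i + 1L, j + 1L]) -
        (xp[i - 1L, j - 1L] + 2 * xp[i - 1L, j] + xp[i - 1L, j + 1L])
  list(gx = gx, gy = gy)
}

#' Binary Canny edge map (internal)
#' @noRd
cannyEdges <- function(v, sigma = 1, low = 0.1, high = 0.2) {
  h <- nrow(v); w <- ncol(v)
  if (h < 3L || w < 3L) return(matrix(FALSE, h, w))
  sm <- gaussBlur(v, sigma)
  g <- .sobel(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, h, w))
  mag <- mag / mx
  # quantize gradient direction to 0 / 45 / 90 / 135 degrees
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4L) + 1L
  mp <- padMatrix(mag, 1L)
  i <- 2:(h + 1L); j <- 2:(w + 1L)
  nbr <- list(
    list(mp[i, j - 1L], mp[i, j + 1L]),              # 0 deg: left/right
    list(mp[i - 1L, j + 1L], mp[i + 1L, j - 1L]),    # 45 deg
    list(mp[i - 1L, j], mp[i + 1L, j]),              # 90 deg: up/down
    list(mp[i - 1L, j - 1L], mp[i + 1L, j + 1L]))    # 135 deg
  keep <- matrix(FALSE, h, w)
  for (s in 1:4) {
    sel <- sector == s
    keep[sel] <- mag[sel] >= nbr[[s]][[1L]][sel] & mag[sel] >= nbr[[s]][[2L]][sel]
  }
  nms <- mag * keep
  strong <- nms >= high
  weak <- nms >= low & !strong
  # hysteresis: grow strong edges through connected weak pixels (8-neighbour)
  repeat {
    sp <- padMatrix(strong, 1L) > 0
    dil <- sp[i - 1L, j - 1L] | sp[i - 1L, j] | sp[i - 1L, j + 1L] |
           sp[i, j - 1L] | sp[i, j + 1L] |
           sp[i + 1L, j - 1L] | sp[i + 1L, j] | sp[i + 1L, j + 1L]
    grown <- strong | (weak & dil)
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}
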