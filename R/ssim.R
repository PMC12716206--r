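# Structural similarity core. Mean SSIM over all fully-contained uniform
# windows with unbiased (co)variance normalization -- the same definition as
# the standard reference implementation (scikit-image structural_similarity
# with a uniform window), so cross-implementation tests can require exact
# agreement. The analytic gradient with respect to the second image drives
# the structural term of the training loss; it is validated against finite
# differences in the test suite.

# window-level statistics shared by value and gradient computations
.ssimStats <- function(x, y, window, dataRange = 1) {
  k <- as.integer(window)
  stopifnot(k %% 2L == 1L, k >= 3L)
  if (k > nrow(x) || k > ncol(x))
    psStop("ps_parameter_error", "SSIM window larger than image")
  N <- k * k
  covNorm <- N / (N - 1)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  ux <- boxSumValid(x, k) / N
  uy <- boxSumValid(y, k) / N
  vx <- covNorm * (boxSumValid(x * x, k) / N - ux * ux)
  vy <- covNorm * (boxSumValid(y * y, k) / N - uy * uy)
  vxy <- covNorm * (boxSumValid(x * y, k) / N - ux * uy)
  A1 <- 2 * ux * uy + C1
  A2 <- 2 * vxy + C2
  B1 <- ux^2 + uy^2 + C1
  B2 <- vx + vy + C2
  list(k = k, N = N, covNorm = covNorm, ux = ux, uy = uy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, S = (A1 * A2) / (B1 * B2))
}

#' Mean SSIM between two equally sized matrices (internal core)
#' @noRd
ssimCore <- function(x, y, window = 7L, dataRange = 1) {
  mean(.ssimStats(x, y, window, dataRange)$S)
}

#' Gradient of mean SSIM(x, y) with respect to y (internal core)
#'
#' d meanS / dy decomposes into window-level partials against the window mean,
#' variance and covariance of y; each scatters back to pixels through the
#' adjoint box filter.
#' @noRd
ssimGradCore <- function(x, y, window = 7L, dataRange = 1) {
  .ssimGradFromStats(x, y, .ssimStats(x, y, window, dataRange))
}

#' Mean SSIM and its gradient from one pass of window statistics
#' @noRd
ssimValGradCore <- function(x, y, window = 7L, dataRange = 1) {
  st <- .ssimStats(x, y, window, dataRange)
  list(mssim = mean(st$S), grad = .ssimGradFromStats(x, y, st))
}

.ssimGradFromStats <- function(x, y, st) {
  k <- st$k
  N <- st$N
  c <- st$covNorm
  P <- length(st$S)
  G1 <- (2 * st$ux * st$A2) / (st$B1 * st$B2) - st$S * (2 * st$uy) / st$B1
  G2 <- -st$S / st$B2
  G3 <- (2 * st$A1) / (st$B1 * st$B2)
  hatG1 <- boxSumAdjoint(G1, k)
  hatG2 <- boxSumAdjoint(G2, k)
  hatG2uy <- boxSumAdjoint(G2 * st$uy, k)
  hatG3 <- boxSumAdjoint(G3, k)
  hatG3ux <- boxSumAdjoint(G3 * st$ux, k)
  (hatG1 + 2 * c * (y * hatG2 - hatG2uy) + c * (x * hatG3 - hatG3ux)) / (P * N)
}
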