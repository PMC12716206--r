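# The evaluation suite: pixel MSE, PSNR against the maximum possible pixel
# value, mean SSIM, Pearson correlation, Canny edge density and the
# high-frequency content ratio, plus single-pair and batch report
# aggregation.

.asMat <- function(x) if (methods::is(x, "HeightMap")) x@values else as.matrix(x)

.checkCongruent <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    psStop("ps_dimension_error", "images must have equal dimensions")
}

#' Mean squared error between two images
#'
#' @param a,b \linkS4class{HeightMap}s or matrices of equal size.
#' @return mean over all pixels of the squared difference.
#' @export
mseMetric <- function(a, b) {
  a <- .asMat(a); b <- .asMat(b)
  .checkCongruent(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' \code{10 * log10(maxI^2 / MSE)}; \code{maxI} defaults to 1, the maximum
#' possible value of a unit-normalized image. Identical images give
#' \code{Inf}.
#'
#' @param a,b images of equal size.
#' @param maxI maximum possible pixel value (> 0).
#' @return PSNR in dB (\code{Inf} when MSE = 0).
#' @export
psnrMetric <- function(a, b, maxI = 1) {
  if (maxI <= 0) psStop("ps_parameter_error", "maxI must be positive")
  m <- mseMetric(a, b)
  if (m == 0) return(Inf)
  10 * log10(maxI^2 / m)
}

#' Mean structural similarity index
#'
#' Standard SSIM averaged over all fully-contained uniform windows with
#' stabilizing constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 for data range
#' L = 1, and unbiased (co)variances -- numerically identical to the common
#' reference implementation with a uniform window.
#'
#' @param a,b unit-range images of equal size.
#' @param window odd window size (default 7).
#' @param dataRange data range L (default 1).
#' @return scalar in [-1, 1].
#' @export
ssimMetric <- function(a, b, window = 7L, dataRange = 1) {
  a <- .asMat(a); b <- .asMat(b)
  .checkCongruent(a, b)
  ssimCore(a, b, window, dataRange)
}

#' Pearson correlation over flattened pixel pairs
#'
#' @param a,b images of equal size; both must be non-constant.
#' @return scalar in [-1, 1].
#' @export
pearsonMetric <- function(a, b) {
  a <- .asMat(a); b <- .asMat(b)
  .checkCongruent(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    psStop("ps_undefined_error", "correlation undefined for a constant image")
  stats::cor(as.vector(a), as.vector(b))
}

#' Canny edge density
#'
#' Fraction of pixels flagged as edges by a Canny detector (Gaussian
#' smoothing, Sobel gradients, non-maximum suppression, hysteresis with
#' thresholds on the gradient magnitude normalized to its maximum). Used as
#' a proxy for preservation of fine structure; comparisons are relative, so
#' only consistency of the parameters matters.
#'
#' @param h a unit-normalized \linkS4class{HeightMap} or matrix.
#' @param sigma Gaussian smoothing sd in pixels (default 1).
#' @param thresholds hysteresis (low, high) on normalized gradient magnitude
#'   (default c(0.1, 0.2)).
#' @return fraction of edge pixels in [0, 1].
#' @export
edgeDensity <- function(h, sigma = 1, thresholds = c(0.1, 0.2)) {
  v <- .asMat(h)
  mean(cannyEdges(v, sigma, thresholds[1L], thresholds[2L]))
}

#' High-frequency content ratio f_R / f_O
#'
#' f(.) is the total 2D spectral magnitude above a radial frequency cutoff
#' (a fraction of Nyquist; DC excluded). Values below 1 indicate lost
#' high-frequency detail in the reconstruction, above 1 added high-frequency
#' energy.
#'
#' @param recon reconstructed image.
#' @param orig original image (non-constant).
#' @param cutoff radial cutoff as a fraction of Nyquist (default 0.25).
#' @return non-negative scalar; 1 when \code{recon} equals \code{orig}.
#' @export
frequencyRatio <- function(recon, orig, cutoff = 0.25) {
  r <- .asMat(recon); o <- .asMat(orig)
  .checkCongruent(r, o)
  hf <- function(x) {
    m <- nrow(x); n <- ncol(x)
    fy <- c(seq(0, floor(m / 2)), seq(-(ceiling(m / 2) - 1), -1)) / m
    fx <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
    rad <- sqrt(outer(fy^2, fx^2, "+"))
    keep <- rad > cutoff * 0.5
    sum(Mod(stats::fft(x))[keep])
  }
  fo <- hf(o)
  if (fo == 0)
    psStop("ps_undefined_error", "frequency content of the original is zero")
  hf(r) / fo
}

.metricRow <- function(orig, recon, ssimWindow = 7L, cannySigma = 1,
                       cannyThresholds = c(0.1, 0.2), freqCutoff = 0.25) {
  data.frame(
    mse = mseMetric(orig, recon),
    psnr = psnrMetric(orig, recon),
    ssim = ssimMetric(orig, recon, ssimWindow),
    pearson = pearsonMetric(orig, recon),
    edge_density_orig = edgeDensity(orig, cannySigma, cannyThresholds),
    edge_density_recon = edgeDensity(recon, cannySigma, cannyThresholds),
    freq_ratio = frequencyRatio(recon, orig, freqCutoff))
}

#' Evaluate one original/reconstruction pair
#'
#' Computes the full metric panel consistently from one pair.
#'
#' @param orig,recon unit-normalized images of equal size.
#' @param ssimWindow SSIM window (default 7).
#' @param cannySigma,cannyThresholds Canny parameters.
#' @param freqCutoff radial cutoff for the frequency-content ratio.
#' @return a \linkS4class{MetricsReport} with n = 1.
#' @export
evaluatePair <- function(orig, recon, ssimWindow = 7L, cannySigma = 1,
                         cannyThresholds = c(0.1, 0.2), freqCutoff = 0.25) {
  methods::new("MetricsReport",
               metrics = .metricRow(orig, recon, ssimWindow, cannySigma,
                                    cannyThresholds, freqCutoff),
               n = 1L)
}

#' Evaluate a batch of original/reconstruction pairs
#'
#' @param origs,recons lists of images, pairwise congruent.
#' @param ... passed to [evaluatePair()].
#' @return a \linkS4class{MetricsReport}; use [metricSummary()] for
#'   mean +/- SD.
#' @export
evaluateBatch <- function(origs, recons, ...) {
  stopifnot(length(origs) == length(recons), length(origs) >= 1L)
  rows <- do.call(rbind, Map(function(o, r) .metricRow(o, r, ...), origs, recons))
  methods::new("MetricsReport", metrics = rows, n = length(origs))
}
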