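# Masking-fraction sweeps and continuous 3-segment piecewise-linear
# regression to locate the break-points where reconstruction quality changes
# slope.

#' Sweep masking fractions and evaluate reconstruction quality
#'
#' For every fraction and replicate, draws a fresh random line mask,
#' simulates partial acquisition, reconstructs with the model and evaluates
#' the pair; results are aggregated as mean and SD per fraction.
#' Deterministic for a fixed seed.
#'
#' @param model a trained \linkS4class{InpaintingModel}.
#' @param testImages list of unit-normalized \linkS4class{HeightMap}s.
#' @param fractions masking fractions to test (default 0.05 to 0.90 by 0.05).
#' @param replicates replicate masks per fraction (default 3).
#' @param seed RNG seed.
#' @param metrics which metric columns to aggregate.
#' @return a \linkS4class{SweepResult}.
#' @export
maskingSweep <- function(model, testImages, fractions = seq(0.05, 0.90, by = 0.05),
                         replicates = 3L, seed = 1L,
                         metrics = c("psnr", "mse", "ssim", "pearson")) {
  stopifnot(length(testImages) >= 1L)
  if (is.unsorted(fractions, strictly = TRUE))
    psStop("ps_parameter_error", "fractions must be strictly increasing")
  m <- nrow(testImages[[1L]]@values)
  rows <- list()
  for (fi in seq_along(fractions)) {
    p <- fractions[fi]
    vals <- matrix(NA_real_, replicates, length(metrics),
                   dimnames = list(NULL, metrics))
    for (r in seq_len(replicates)) {
      perImage <- vapply(seq_along(testImages), function(ii) {
        img <- testImages[[ii]]
        lm <- randomLineMask(m, p,
                             seed = subSeed(seed, fi * 100000L + r * 1000L + ii))
        acq <- acquirePartial(img, lm)
        rec <- reconstruct(model, acq$partial, acq$mask)
        c(psnr = psnrMetric(img, rec), mse = mseMetric(img, rec),
          ssim = ssimMetric(img, rec), pearson = pearsonMetric(img, rec))
      }, c(psnr = 0, mse = 0, ssim = 0, pearson = 0))
      vals[r, ] <- rowMeans(perImage)[metrics]
    }
    for (mt in metrics) {
      v <- vals[, mt]
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = p, metric = mt, mean = mean(v),
        # identical replicates (e.g. all Inf PSNR at fraction 0) have zero SD
        sd = if (replicates > 1L && length(unique(v)) > 1L) stats::sd(v) else 0,
        n = replicates)
    }
  }
  methods::new("SweepResult", table = do.call(rbind, rows),
               replicates = as.integer(replicates))
}

# OLS of y on the continuous broken-line basis {1, x, (x-c1)+, (x-c2)+}
.brokenLineFit <- function(x, y, c1, c2) {
  X <- cbind(1, x, pmax(x - c1, 0), pmax(x - c2, 0))
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss)
}

#' Continuous 3-segment piecewise-linear regression
#'
#' Least-squares fit of a continuous broken line with exactly two interior
#' break-points: a coarse grid search over break-point pairs (each candidate
#' solved by OLS in the broken-line basis) followed by Nelder-Mead
#' refinement. On noiseless segmented input the solver recovers the break
#' abscissae essentially exactly. Near-collinear data are flagged as
#' non-identifiable.
#'
#' @param x strictly increasing abscissae (masking fractions), length >= 9.
#' @param y metric means at \code{x}.
#' @param gridSize coarse grid resolution per break-point (default 50).
#' @return a \linkS4class{BreakpointFit}; break-points ascending
#'   (primary, secondary).
#' @export
segmentedFit <- function(x, y, gridSize = 50L) {
  if (length(x) != length(y)) psStop("ps_dimension_error", "x and y lengths differ")
  if (length(x) < 9L) psStop("ps_data_error", "need at least 9 points for 3 segments")
  if (is.unsorted(x, strictly = TRUE))
    psStop("ps_parameter_error", "x must be strictly increasing")
  ok <- is.finite(y)
  if (!all(ok)) {
    x <- x[ok]; y <- y[ok]
    if (length(x) < 9L) psStop("ps_data_error", "too few finite points")
  }
  n <- length(x)
  # candidate breaks strictly inside, leaving >= 2 points per outer segment
  lo <- x[3L]
  hi <- x[n - 2L]
  grid <- seq(lo, hi, length.out = gridSize)
  best <- list(rss = Inf, c1 = NA_real_, c2 = NA_real_)
  for (i in seq_len(gridSize - 1L)) {
    for (j in (i + 1L):gridSize) {
      f <- .brokenLineFit(x, y, grid[i], grid[j])
      if (f$rss < best$rss) best <- list(rss = f$rss, c1 = grid[i], c2 = grid[j])
    }
  }
  eps <- (hi - lo) / (2 * gridSize)
  obj <- function(par) {
    c1 <- min(par); c2 <- max(par)
    if (c1 < lo || c2 > hi || (c2 - c1) < eps) return(1e12 + (c1 - c2)^2)
    .brokenLineFit(x, y, c1, c2)$rss
  }
  opt <- stats::optim(c(best$c1, best$c2), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000L))
  c1 <- min(opt$par); c2 <- max(opt$par)
  f <- .brokenLineFit(x, y, c1, c2)
  beta <- unname(f$coef)
  slopes <- c(beta[2L], beta[2L] + beta[3L], beta[2L] + beta[3L] + beta[4L])
  intercepts <- c(beta[1L],
                  beta[1L] - beta[3L] * c1,
                  beta[1L] - beta[3L] * c1 - beta[4L] * c2)
  # guard the nested-model property: never worse than the best single line
  line <- stats::lm.fit(cbind(1, x), y)
  lineRss <- sum(line$residuals^2)
  rss <- min(f$rss, lineRss)
  tss <- sum((y - mean(y))^2)
  # identifiability: does the broken line explain materially more than a line,
  # and are the slope changes non-negligible?
  slopeScale <- max(abs(slopes), diff(range(y)) / diff(range(x)), 1e-12)
  identifiable <- (lineRss - f$rss) > max(1e-10, 1e-6 * max(tss, 1e-12)) &&
    max(abs(diff(slopes))) > 1e-6 * slopeScale
  methods::new("BreakpointFit", breakpoints = c(c1, c2), slopes = slopes,
               intercepts = intercepts, residual = f$rss,
               r2 = if (tss > 0) 1 - rss / tss else 1,
               identifiable = identifiable, x = x, y = y)
}

#' Predict from a BreakpointFit
#' @param object a \linkS4class{BreakpointFit}.
#' @param newx abscissae.
#' @return fitted values.
#' @export
predictSegments <- function(object, newx) {
  b <- object@breakpoints
  seg <- findInterval(newx, b) + 1L
  object@intercepts[seg] + object@slopes[seg] * newx
}
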