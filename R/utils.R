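# Internal helpers shared across modules: scoped RNG, sub-seed derivation,
# padding and fast box / Gaussian filtering used by the SSIM core, the scene
# generator and the Canny detector.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Counter-based sub-seed derivation.
#'
#' Scene k of a dataset uses subSeed(seed, k), so datasets are extensible
#' (adding scenes never reshuffles earlier ones) and scenes are independent.
#' @noRd
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k) * 100003) %% 2147483587L)
}

#' Round half up (the convention used for masked-line counts)
#' @noRd
roundHalfUp <- function(x) floor(x + 0.5)

#' Zero-pad a matrix by p on all sides
#' @noRd
padMatrix <- function(x, p) {
  out <- matrix(0, nrow(x) + 2L * p, ncol(x) + 2L * p)
  out[(p + 1L):(p + nrow(x)), (p + 1L):(p + ncol(x))] <- x
  out
}

#' Zero-pad a (H, W, C) array by p on the two spatial dims
#' @noRd
padArray <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), ] <- x
  out
}

#' Replicate-pad (edge extend) a matrix by p on all sides
#' @noRd
padReplicate <- function(x, p) {
  ri <- c(rep(1L, p), seq_len(nrow(x)), rep(nrow(x), p))
  ci <- c(rep(1L, p), seq_len(ncol(x)), rep(ncol(x), p))
  x[ri, ci, drop = FALSE]
}

#' Sliding-window sums over all fully-contained k x k windows (valid mode),
#' via a summed-area table. Input H x W, output (H-k+1) x (W-k+1).
#' @noRd
boxSumValid <- function(x, k) {
  stopifnot(k >= 1L, k <= nrow(x), k <= ncol(x))
  .boxSumValidCpp(x, as.integer(k))
}

#' Pure-R summed-area-table reference for the compiled box filter
#' @noRd
boxSumValidR <- function(x, k) {
  h <- nrow(x)
  w <- ncol(x)
  stopifnot(k >= 1L, k <= h, k <= w)
  s <- matrix(0, h + 1L, w + 1L)
  s[-1L, -1L] <- x
  s <- apply(s, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  i <- seq_len(h - k + 1L)
  j <- seq_len(w - k + 1L)
  s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
    s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]
}

#' Adjoint of boxSumValid: scatter window-level values back to the pixels
#' they cover. Input (H-k+1) x (W-k+1), output H x W where out[a, b] is the
#' sum of g over all windows containing (a, b).
#' @noRd
boxSumAdjoint <- function(g, k) {
  p <- k - 1L
  gp <- matrix(0, nrow(g) + 2L * p, ncol(g) + 2L * p)
  gp[(p + 1L):(p + nrow(g)), (p + 1L):(p + ncol(g))] <- g
  boxSumValid(gp, k)
}

#' 1D Gaussian kernel with radius ceiling(3 sigma)
#' @noRd
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with replicate (edge-extend) padding
#' @noRd
gaussBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussKernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  xp <- padReplicate(x, r)
  # filter columns then rows using stats::filter on the padded matrix
  tmp <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2L))
  tmp <- tmp[(r + 1L):(r + nrow(x)), , drop = FALSE]
  out <- t(apply(tmp, 1L, function(row) stats::filter(row, k, sides = 2L)))
  out[, (r + 1L):(r + ncol(x)), drop = FALSE]
}

#' Stop with a classed error (used so callers/tests can distinguish causes)
#' @noRd
psStop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
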