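# Line masks: which slow-axis lines are scanned (kept) versus skipped.
#
# Conventions shared by every generator:
#   * exactly round(p * m) lines are skipped (round half up);
#   * the first and last lines are always scanned, anchoring both linear
#     interpolation and the inpainting boundary;
#   * skipped lines are drawn from the interior lines 2..(m-1).

.newLineMask <- function(keep, fraction, pattern, maxConsecutive = Inf,
                         seed = NA_real_) {
  methods::new("LineMask", keep = keep, fraction = fraction, pattern = pattern,
               maxConsecutive = maxConsecutive, seed = seed)
}

.maskCount <- function(m, p) as.integer(roundHalfUp(p * m))

.checkMaskFeasible <- function(m, p, maxConsecutive = Inf) {
  if (m < 4L) psStop("ps_parameter_error", "need at least 4 lines")
  if (p < 0 || p >= 1) psStop("ps_parameter_error", "fraction must be in [0, 1)")
  k <- .maskCount(m, p)
  if (k > m - 2L)
    psStop("ps_infeasible_error",
           sprintf("cannot skip %d of %d lines with scanned borders", k, m))
  if (is.finite(maxConsecutive)) {
    # runs of <= c skips need at least ceiling(k / c) - 1 kept separators
    if (k + ceiling(k / maxConsecutive) - 1 > m - 2L)
      psStop("ps_infeasible_error",
             sprintf("max_consecutive = %d infeasible for m = %d, p = %.3g",
                     maxConsecutive, m, p))
  }
  k
}

.longestZeroRun <- function(keep) {
  r <- rle(keep)
  z <- r$lengths[!r$values]
  if (length(z)) max(z) else 0L
}

#' Random line mask
#'
#' Skips exactly \code{round(p * m)} interior lines chosen uniformly at
#' random. With \code{maxConsecutive} set, draws violating the run-length
#' limit are rejected and redrawn (the run-limited policy that avoids losing
#' excessive information in one region).
#'
#' @param m number of scan lines (>= 4).
#' @param p masked fraction in [0, 1).
#' @param maxConsecutive maximum allowed run of consecutive skipped lines
#'   (default \code{Inf} = unlimited).
#' @param seed RNG seed.
#' @return a \linkS4class{LineMask}.
#' @examples
#' lm <- randomLineMask(256, 0.30, seed = 1)
#' sum(!maskKeep(lm))  # 77
#' @export
randomLineMask <- function(m, p, maxConsecutive = Inf, seed = 1L) {
  m <- as.integer(m)
  k <- .checkMaskFeasible(m, p, maxConsecutive)
  pattern <- if (is.finite(maxConsecutive)) "random_limited" else "random"
  keep <- withSeed(seed, {
    for (attempt in seq_len(10000L)) {
      skip <- sample(2:(m - 1L), k)
      kv <- rep(TRUE, m)
      kv[skip] <- FALSE
      if (.longestZeroRun(kv) <= maxConsecutive) break
      kv <- NULL
    }
    kv
  })
  if (is.null(keep))
    psStop("ps_infeasible_error",
           "could not draw a mask satisfying max_consecutive")
  .newLineMask(keep, p, pattern, maxConsecutive, as.numeric(seed))
}

# most-even interior placement used by fixed_distance and for block starts
.evenPositions <- function(m, k) {
  pos <- roundHalfUp(1 + seq_len(k) * (m - 1) / (k + 1))
  pos <- pmin(pmax(pos, 2L), m - 1L)
  # resolve rounding collisions while keeping positions interior and sorted
  for (i in seq_len(k)) {
    if (i > 1L && pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  }
  if (any(pos > m - 1L))
    psStop("ps_infeasible_error", "cannot place skipped lines in the interior")
  as.integer(pos)
}

#' Deterministic patterned line masks
#'
#' Three controlled masking patterns over the interior lines, all hitting the
#' exact skip count \code{round(p * m)}:
#' \describe{
#'   \item{fixed_distance}{single skipped lines at maximally even spacing.}
#'   \item{geometric}{gaps between consecutive skipped lines grow
#'     geometrically (ratio \code{ratio}), renormalized so the last skip
#'     stays interior.}
#'   \item{block}{skips grouped into contiguous runs of \code{blockLength}
#'     (the final block may be shorter), blocks spread evenly.}
#' }
#' These definitions are this package's own constructions of the named
#' pattern families.
#'
#' @param m number of scan lines.
#' @param p masked fraction in [0, 1).
#' @param pattern \code{"fixed_distance"}, \code{"geometric"} or
#'   \code{"block"}.
#' @param ratio gap growth ratio for \code{geometric} (default 1.4).
#' @param blockLength run length for \code{block} (default 4).
#' @return a \linkS4class{LineMask}.
#' @export
patternedLineMask <- function(m, p, pattern = c("fixed_distance", "geometric", "block"),
                              ratio = 1.4, blockLength = 4L) {
  pattern <- match.arg(pattern)
  m <- as.integer(m)
  k <- .checkMaskFeasible(m, p)
  keep <- rep(TRUE, m)
  if (k > 0L) {
    skip <- switch(pattern,
      fixed_distance = .evenPositions(m, k),
      geometric = {
        if (ratio <= 0) psStop("ps_parameter_error", "ratio must be positive")
        raw <- ratio^(0:k)
        cum <- cumsum(raw)[seq_len(k)]
        pos <- roundHalfUp(1 + cum / sum(raw) * (m - 1))
        pos <- pmin(pmax(pos, 2L), m - 1L)
        for (i in seq_len(k)) {
          if (i > 1L && pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
        }
        if (any(pos > m - 1L))
          psStop("ps_infeasible_error", "geometric pattern infeasible for (m, p)")
        as.integer(pos)
      },
      block = {
        blockLength <- as.integer(blockLength)
        if (blockLength < 1L) psStop("ps_parameter_error", "blockLength must be >= 1")
        nb <- ceiling(k / blockLength)
        lens <- rep(blockLength, nb)
        lens[nb] <- k - blockLength * (nb - 1L)
        # spread block centres evenly, then expand to runs
        centres <- .evenPositions(m, nb)
        pos <- integer(0L)
        cursor <- 2L
        for (b in seq_len(nb)) {
          start <- max(cursor, centres[b] - (lens[b] - 1L) %/% 2L)
          if (start + lens[b] - 1L > m - 1L) start <- m - 1L - lens[b] + 1L
          if (start < cursor)
            psStop("ps_infeasible_error", "block pattern infeasible for (m, p)")
          pos <- c(pos, start:(start + lens[b] - 1L))
          cursor <- start + lens[b] + 1L  # leave a scanned separator
        }
        pos
      })
    if (length(unique(skip)) != k || any(skip < 2L) || any(skip > m - 1L))
      psStop("ps_infeasible_error", sprintf("%s pattern infeasible", pattern))
    keep[skip] <- FALSE
  }
  .newLineMask(keep, p, pattern)
}

#' @rdname expandMask
#' @export
setMethod("expandMask", "LineMask", function(lm, n) {
  n <- as.integer(n)
  MaskRaster(matrix(as.numeric(lm@keep), length(lm@keep), n))
})

#' Detect scan-line artifacts (scars) and return them as a mask
#'
#' A row is flagged as scarred when it is displaced, as a whole, from the
#' heights its vertical neighbourhood predicts. Detection is two-pass.
#' Pass one compares each row column-wise to the median of the rows at
#' distance 2 to 4 on either side (immediate neighbours are excluded so that
#' multi-line scars do not mask themselves) and flags candidates by a robust
#' z-score (median absolute deviation across rows) with a column-support
#' requirement. Pass two re-scores every row against its nearest rows that
#' are clean according to pass one, which removes the reference
#' contamination that multi-row scar bands cause in their vicinity. Rows
#' with |z| > \code{zThresh} deviating beyond the column-wise noise scale
#' over at least \code{minScarCols} columns are flagged. The returned
#' \linkS4class{LineMask} (keep = 0 on scarred rows) is directly usable for
#' mask-aware inpainting.
#'
#' @param h a \linkS4class{HeightMap} (raw or normalized) with >= 5 rows.
#' @param zThresh robust z threshold on the per-row offset (default 6).
#' @param minScarCols minimum number of deviating columns (default a quarter
#'   of the width).
#' @return a \linkS4class{LineMask} with pattern \code{"scar"}.
#' @export
extractScarMask <- function(h, zThresh = 6, minScarCols = NULL) {
  stopifnot(methods::is(h, "HeightMap"))
  v <- h@values
  m <- nrow(v)
  n <- ncol(v)
  if (m < 5L) psStop("ps_parameter_error", "need at least 5 rows")
  if (is.null(minScarCols)) minScarCols <- max(4L, n %/% 4L)

  scoreAgainst <- function(refRows) {
    ref <- matrix(0, m, n)
    for (i in seq_len(m)) {
      nb <- refRows(i)
      ref[i, ] <- if (length(nb) == 1L) v[nb, ] else
        apply(v[nb, , drop = FALSE], 2L, stats::median)
    }
    dev <- v - ref
    rowOffset <- apply(dev, 1L, stats::median)
    list(dev = dev, rowOffset = rowOffset)
  }
  flagRows <- function(sc, cleanIdx) {
    scale <- stats::mad(sc$rowOffset[cleanIdx])
    colScale <- stats::mad(as.vector(sc$dev[cleanIdx, , drop = FALSE]))
    if (scale <= .Machine$double.eps && colScale <= .Machine$double.eps)
      return(rep(FALSE, m))  # constant or noiseless image: nothing deviates
    scale <- max(scale, 1e-12)
    colScale <- max(colScale, 1e-12)
    z <- abs(sc$rowOffset) / scale
    ncolsDev <- rowSums(abs(sc$dev) > zThresh * colScale)
    z > zThresh & ncolsDev >= minScarCols
  }

  # pass 1: distant symmetric neighbourhood (distance 2..4)
  sc1 <- scoreAgainst(function(i)
    intersect(c((i - 4L):(i - 2L), (i + 2L):(i + 4L)), seq_len(m)))
  cand <- flagRows(sc1, seq_len(m))

  # pass 2: re-score against the nearest rows judged clean in pass 1
  clean <- which(!cand)
  if (length(clean) >= 2L && any(cand)) {
    sc2 <- scoreAgainst(function(i) {
      others <- clean[clean != i]
      below <- rev(others[others < i])
      above <- others[others > i]
      c(utils::head(below, 2L), utils::head(above, 2L))
    })
    scarred <- flagRows(sc2, clean)
  } else {
    scarred <- cand
  }
  .newLineMask(!scarred, mean(scarred), "scar")
}
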