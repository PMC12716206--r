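# Non-learned reconstruction baselines: column-wise linear interpolation
# along the slow axis (the minimum baseline for skipped lines) and median
# line correction (the conventional scar treatment).

#' Fill skipped lines by linear interpolation along the slow axis
#'
#' Each skipped row is interpolated per column between the nearest scanned
#' rows above and below. Requires scanned first and last rows (which every
#' acquisition mask guarantees).
#'
#' @param partial a \linkS4class{HeightMap} with skipped rows at the
#'   placeholder value.
#' @param mask the matching \linkS4class{MaskRaster} or
#'   \linkS4class{LineMask}.
#' @return a \linkS4class{HeightMap} with all rows filled.
#' @export
interpolateLinear <- function(partial, mask) {
  stopifnot(methods::is(partial, "HeightMap"))
  keep <- if (methods::is(mask, "LineMask")) mask@keep else mask@values[, 1L] > 0.5
  v <- partial@values
  if (length(keep) != nrow(v))
    psStop("ps_dimension_error", "mask length must equal row count")
  if (!keep[1L] || !keep[length(keep)])
    psStop("ps_precondition_error",
           "first and last rows must be scanned for interpolation")
  scanned <- which(keep)
  if (length(scanned) < length(keep)) {
    for (g in seq_len(length(scanned) - 1L)) {
      a <- scanned[g]
      b <- scanned[g + 1L]
      if (b - a > 1L) {
        for (r in (a + 1L):(b - 1L)) {
          w <- (r - a) / (b - a)
          v[r, ] <- (1 - w) * v[a, ] + w * v[b, ]
        }
      }
    }
  }
  HeightMap(v, pixelSize = partial@pixelSize, normState = partial@normState,
            normParams = partial@normParams)
}

#' Median line correction of scarred rows
#'
#' Each flagged row is replaced by the per-column median of the nearest
#' \code{k} clean rows above and the nearest \code{k} below (with the default
#' \code{k = 1} this is the midpoint of the two neighbouring lines, the
#' classic median-line scar treatment). If a flagged row has clean rows on
#' one side only, that side's rows are used; a map with no clean rows at all
#' is an error.
#'
#' @param h a \linkS4class{HeightMap}.
#' @param scarMask a \linkS4class{LineMask} with keep = 0 on scarred rows.
#' @param k clean neighbours per side (default 1).
#' @return the corrected \linkS4class{HeightMap}.
#' @export
medianLineCorrect <- function(h, scarMask, k = 1L) {
  stopifnot(methods::is(h, "HeightMap"), methods::is(scarMask, "LineMask"))
  v <- h@values
  keep <- scarMask@keep
  if (length(keep) != nrow(v))
    psStop("ps_dimension_error", "mask length must equal row count")
  if (!any(keep))
    psStop("ps_correction_error", "no clean rows available for correction")
  clean <- which(keep)
  for (r in which(!keep)) {
    above <- rev(clean[clean < r])
    below <- clean[clean > r]
    nb <- c(utils::head(above, k), utils::head(below, k))
    if (length(nb) == 0L)
      psStop("ps_correction_error",
             sprintf("row %d has no clean neighbour on either side", r))
    v[r, ] <- if (length(nb) == 1L) v[nb, ] else
      apply(v[nb, , drop = FALSE], 2L, stats::median)
  }
  HeightMap(v, pixelSize = h@pixelSize, normState = h@normState,
            normParams = h@normParams)
}
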