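# Generics for the verbs that dispatch on the package's classes.

#' Min-max normalize a raw height map to [0, 1]
#'
#' Per-image min-max rescaling; the original (min, max) is recorded so
#' [denormalizeMap()] inverts it exactly. A constant image maps to all zeros
#' with a recorded unit span (min, min + 1), avoiding division by zero.
#'
#' @param h a raw \linkS4class{HeightMap}.
#' @return a unit-normalized \linkS4class{HeightMap}.
#' @examples
#' h <- HeightMap(matrix(c(0, 5, 10, 20), 2))
#' heights(normalizeMap(h))
#' @export
setGeneric("normalizeMap", function(h) standardGeneric("normalizeMap"))

#' Invert min-max normalization
#' @param h a unit-normalized \linkS4class{HeightMap}.
#' @return the raw-unit \linkS4class{HeightMap}.
#' @export
setGeneric("denormalizeMap", function(h) standardGeneric("denormalizeMap"))

#' Expand a per-line mask to a 2D binary raster
#' @param lm a \linkS4class{LineMask}.
#' @param n number of columns (fast-axis pixels).
#' @return a \linkS4class{MaskRaster} whose row i is constantly keep[i].
#' @export
setGeneric("expandMask", function(lm, n) standardGeneric("expandMask"))

#' Simulate partial acquisition of a height map under a line mask
#'
#' Scanned rows are copied verbatim (bit-exact); skipped rows are set to the
#' placeholder value 0 in normalized units.
#'
#' @param h a unit-normalized \linkS4class{HeightMap}.
#' @param lm a \linkS4class{LineMask} with one entry per row of \code{h}.
#' @return list with elements \code{partial} (\linkS4class{HeightMap}) and
#'   \code{mask} (\linkS4class{MaskRaster}).
#' @export
setGeneric("acquirePartial", function(h, lm) standardGeneric("acquirePartial"))

#' Reconstruct the skipped lines of a partial scan
#'
#' Runs the encoder-decoder forward pass and composites: scanned rows are
#' copied verbatim from the acquired data, only skipped rows carry the network
#' prediction; the result is clipped to [0, 1].
#'
#' @param model a trained \linkS4class{InpaintingModel}.
#' @param partial the partially acquired, unit-normalized
#'   \linkS4class{HeightMap} (skipped rows at 0).
#' @param mask the matching \linkS4class{MaskRaster} (or
#'   \linkS4class{LineMask}).
#' @param composite replace valid pixels by acquired data (default TRUE);
#'   set FALSE to obtain the raw network output.
#' @param symmetrize average the network prediction over the four axis
#'   flips of the frame (default TRUE). The scene statistics are symmetric
#'   under both axis reversals, so the average reduces prediction variance
#'   at no training cost.
#' @return a unit-normalized \linkS4class{HeightMap}.
#' @export
setGeneric("reconstruct",
  function(model, partial, mask, composite = TRUE, symmetrize = TRUE)
    standardGeneric("reconstruct"))

#' Mean and standard deviation of each metric in a report
#' @param object a \linkS4class{MetricsReport}.
#' @return named numeric vector (means) / data.frame (summary).
#' @export
setGeneric("metricMeans", function(object) standardGeneric("metricMeans"))

#' @rdname metricMeans
#' @export
setGeneric("metricSummary", function(object) standardGeneric("metricSummary"))

#' Heights matrix of a HeightMap
#' @param h a \linkS4class{HeightMap}.
#' @return numeric matrix.
#' @export
setGeneric("heights", function(h) standardGeneric("heights"))

#' Keep vector of a LineMask
#' @param lm a \linkS4class{LineMask}.
#' @return logical vector (TRUE = scanned).
#' @export
setGeneric("maskKeep", function(lm) standardGeneric("maskKeep"))

#' Masked (skipped) fraction of a LineMask
#' @param lm a \linkS4class{LineMask}.
#' @return numeric.
#' @export
setGeneric("maskFraction", function(lm) standardGeneric("maskFraction"))

#' Break-point abscissae of a segmented fit
#' @param object a \linkS4class{BreakpointFit}.
#' @return numeric length 2 (primary, secondary).
#' @export
setGeneric("breakPoints", function(object) standardGeneric("breakPoints"))
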