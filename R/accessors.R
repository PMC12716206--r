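# Accessors and show methods.

#' @rdname heights
#' @export
setMethod("heights", "HeightMap", function(h) h@values)

#' Dimensions of a HeightMap (rows = slow axis, cols = fast axis)
#' @param x a \linkS4class{HeightMap}.
#' @export
setMethod("dim", "HeightMap", function(x) dim(x@values))

#' Normalization state of a HeightMap
#' @param h a \linkS4class{HeightMap}.
#' @return \code{"raw"} or \code{"unit_normalized"}.
#' @export
normState <- function(h) h@normState

#' Normalization parameters (min, max) of a HeightMap
#' @param h a \linkS4class{HeightMap}.
#' @return numeric length 2.
#' @export
normParams <- function(h) h@normParams

#' Physical pixel size of a HeightMap (micrometres, NA if unknown)
#' @param h a \linkS4class{HeightMap}.
#' @return numeric.
#' @export
pixelSize <- function(h) h@pixelSize

#' @rdname maskKeep
#' @export
setMethod("maskKeep", "LineMask", function(lm) lm@keep)

#' @rdname maskFraction
#' @export
setMethod("maskFraction", "LineMask", function(lm) lm@fraction)

#' Binary matrix of a MaskRaster
#' @param mr a \linkS4class{MaskRaster}.
#' @return numeric 0/1 matrix.
#' @export
maskValues <- function(mr) mr@values

#' @rdname breakPoints
#' @export
setMethod("breakPoints", "BreakpointFit", function(object) object@breakpoints)

#' @rdname metricMeans
#' @export
setMethod("metricMeans", "MetricsReport", function(object) {
  vapply(object@metrics, mean, numeric(1L))
})

#' @rdname metricMeans
#' @export
setMethod("metricSummary", "MetricsReport", function(object) {
  data.frame(metric = names(object@metrics),
             mean = vapply(object@metrics, mean, numeric(1L)),
             sd = vapply(object@metrics, function(x)
               if (length(x) > 1L) stats::sd(x) else 0, numeric(1L)),
             n = object@n, row.names = NULL)
})

#' Per-pair metric table of a MetricsReport
#' @param object a \linkS4class{MetricsReport}.
#' @return data.frame, one row per original/reconstruction pair.
#' @export
metricTable <- function(object) object@metrics

#' Sweep table of a SweepResult
#' @param object a \linkS4class{SweepResult}.
#' @return data.frame (fraction, metric, mean, sd, n).
#' @export
sweepTable <- function(object) object@table

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("HeightMap: %d x %d (%s", d[1L], d[2L], object@normState))
  if (object@normState == "unit_normalized")
    cat(sprintf(", span %.4g..%.4g", object@normParams[1L], object@normParams[2L]))
  cat(sprintf("), range [%.4g, %.4g]\n", min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "LineMask", function(object) {
  cat(sprintf("LineMask: %d lines, %d skipped (p = %.3g), pattern '%s'\n",
              length(object@keep), sum(!object@keep), object@fraction,
              object@pattern))
  invisible(object)
})

setMethod("show", "ScanSignal", function(object) {
  cat(sprintf("ScanSignal: %d samples, line period %.3g s, total %.4g s (%s)\n",
              length(object@time), object@linePeriod, object@totalTime,
              object@rampPolicy))
  invisible(object)
})

setMethod("show", "InpaintingModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(unlist(object@weights, recursive = FALSE), length, numeric(1L)))
  cat(sprintf("InpaintingModel: %s, filters %s, input %dx%d, %s (%d parameters)\n",
              cfg@arch, paste(cfg@filters, collapse = "/"),
              cfg@inputSize[1L], cfg@inputSize[2L],
              if (object@trained) "trained" else "untrained", np))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d pair(s):\n", object@n))
  print(metricSummary(object), digits = 4L)
  invisible(object)
})

setMethod("show", "BreakpointFit", function(object) {
  cat(sprintf("BreakpointFit: breaks at %.4g and %.4g%s, slopes %s, RSS %.3g\n",
              object@breakpoints[1L], object@breakpoints[2L],
              if (object@identifiable) "" else " (not identifiable)",
              paste(sprintf("%.3g", object@slopes), collapse = "/"),
              object@residual))
  invisible(object)
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d fractions x %d metrics, %d replicate(s) each\n",
              length(unique(object@table$fraction)),
              length(unique(object@table$metric)), object@replicates))
  invisible(object)
})
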