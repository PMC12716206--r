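# From a line mask to the instrument side: the modified slow-axis waveform,
# the proportional acquisition-time model, and simulated partial acquisition
# from a fully scanned height map.

#' Build the modified slow-axis (Y) scan waveform for a line mask
#'
#' One line period is spent on each scanned line. During a scanned line the
#' slow-axis position ramps linearly toward the next scanned line, so across
#' a run of k skipped lines the position advances k + 1 line units within a
#' single line period -- a steeper ramp instead of a step, which avoids
#' exciting piezo creep. The waveform is sampled at the segment boundaries
#' (it is piecewise linear in between).
#'
#' @param lm a \linkS4class{LineMask}.
#' @param linePeriod seconds per scanned line.
#' @return a \linkS4class{ScanSignal}; positions are 0-based line units.
#' @examples
#' lm <- randomLineMask(256, 0.30, seed = 1)
#' sig <- buildYSignal(lm, linePeriod = 1159 / 256)
#' @export
buildYSignal <- function(lm, linePeriod = 1) {
  stopifnot(methods::is(lm, "LineMask"))
  scanned <- which(lm@keep) - 1L  # 0-based line positions
  ns <- length(scanned)
  tt <- linePeriod * ns
  # sample at each dwell-segment start plus the end of the final segment,
  # holding the final position
  time <- c(seq_len(ns) - 1L, ns) * linePeriod
  position <- c(scanned, scanned[ns])
  methods::new("ScanSignal", time = as.numeric(time),
               position = as.numeric(position), linePeriod = linePeriod,
               totalTime = tt, rampPolicy = "ramped")
}

#' Write a scan waveform as CSV (t_seconds, y_line_units)
#'
#' @param sig a \linkS4class{ScanSignal}.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writeScanSignal <- function(sig, path) {
  utils::write.csv(data.frame(t_seconds = sig@time, y_line_units = sig@position),
                   path, row.names = FALSE)
  invisible(path)
}

#' Partial-scan acquisition time under the proportional timing model
#'
#' Scanning time is proportional to the scanned-line fraction. Given a
#' \linkS4class{LineMask} the realized fraction \code{scanned / total} is
#' used; given a bare masking fraction p the nominal fraction \code{1 - p}
#' is used. The result is rounded to the nearest second for reporting: a
#' 19 min 19 s full frame (1159 s) at 30\% masking takes 13 min 31 s (811 s).
#'
#' @param lm a \linkS4class{LineMask}, or a numeric masking fraction in
#'   [0, 1).
#' @param fullScanTime seconds for the all-lines scan.
#' @return scan time in seconds (nearest second).
#' @examples
#' partialScanTime(0.30, 1159)  # 811
#' @export
partialScanTime <- function(lm, fullScanTime) {
  if (fullScanTime <= 0) psStop("ps_parameter_error", "fullScanTime must be positive")
  frac <- if (methods::is(lm, "LineMask")) {
    sum(lm@keep) / length(lm@keep)
  } else {
    p <- as.numeric(lm)
    if (p < 0 || p >= 1) psStop("ps_parameter_error", "fraction must be in [0, 1)")
    1 - p
  }
  roundHalfUp(fullScanTime * frac)
}

#' @rdname acquirePartial
#' @export
setMethod("acquirePartial", signature("HeightMap", "LineMask"), function(h, lm) {
  if (h@normState != "unit_normalized")
    psStop("ps_state_error", "acquirePartial expects a normalized height map")
  if (length(lm@keep) != nrow(h@values))
    psStop("ps_dimension_error",
           sprintf("mask has %d lines but map has %d rows",
                   length(lm@keep), nrow(h@values)))
  v <- h@values
  v[!lm@keep, ] <- 0  # placeholder for skipped rows, normalized units
  list(partial = HeightMap(v, pixelSize = h@pixelSize,
                           normState = "unit_normalized",
                           normParams = h@normParams),
       mask = expandMask(lm, ncol(h@values)))
})
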