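# Reading, writing and normalizing height maps and binary masks in plain
# raster exchange formats: 32-bit float single-channel TIFF (archival), CSV
# matrices, and 16-bit grayscale PNG (visualization-grade, quantized).
# Masks travel as 8-bit PNG (255 = scanned) or CSV of 0/1.

.formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         csv = "csv",
         png = "png16",
         psStop("ps_format_error", sprintf("cannot infer format from '%s'", path)))
}

#' Read a height map from disk
#'
#' Supported formats: single-channel float TIFF, CSV matrix, and 16-bit
#' grayscale PNG. Row 1 of the result is the first (top) scanned line and
#' columns run along the fast axis. The map is returned with
#' \code{normState = "raw"}; values are whatever the file stores (PNG reads
#' as \code{[0, 1]}).
#'
#' @param path file to read.
#' @param format \code{"tiff"}, \code{"csv"} or \code{"png16"}; inferred from
#'   the extension by default.
#' @param pixelSize physical pixel size to attach (micrometres, optional).
#' @return a \linkS4class{HeightMap}.
#' @export
readHeightMap <- function(path, format = .formatFromPath(path),
                          pixelSize = NA_real_) {
  if (!file.exists(path))
    psStop("ps_io_error", sprintf("file not found: %s", path))
  format <- match.arg(format, c("tiff", "csv", "png16"))
  v <- switch(format,
    tiff = {
      x <- tryCatch(tiff::readTIFF(path),
                    error = function(e) psStop("ps_format_error",
                      sprintf("unreadable TIFF '%s': %s", path, conditionMessage(e))))
      if (length(dim(x)) == 3L) {
        if (dim(x)[3L] > 1L)
          psStop("ps_channel_error",
                 sprintf("expected single-channel image, got %d channels", dim(x)[3L]))
        x <- x[, , 1L]
      }
      x
    },
    csv = {
      x <- tryCatch(
        as.matrix(utils::read.csv(path, header = FALSE)),
        error = function(e) psStop("ps_format_error",
          sprintf("unreadable CSV '%s': %s", path, conditionMessage(e))))
      storage.mode(x) <- "double"
      dimnames(x) <- NULL
      x
    },
    png16 = {
      x <- tryCatch(png::readPNG(path),
                    error = function(e) psStop("ps_format_error",
                      sprintf("unreadable PNG '%s': %s", path, conditionMessage(e))))
      if (length(dim(x)) == 3L)
        psStop("ps_channel_error",
               sprintf("expected single-channel image, got %d channels", dim(x)[3L]))
      x
    })
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)
    psStop("ps_validation_error",
           sprintf("non-finite pixels, first at [%d, %d] (%d total)",
                   bad[1L, 1L], bad[1L, 2L], nrow(bad)))
  }
  HeightMap(v, pixelSize = pixelSize)
}

#' Write a height map to disk
#'
#' TIFF writes 32-bit float (exact at single precision); CSV writes full
#' double precision (exact round trip); PNG writes 16-bit grayscale after
#' quantization of \code{[0, 1]} values to 65535 levels (maximum absolute
#' round-trip error 1/(2^16 - 1); intended for normalized maps).
#'
#' @param h a \linkS4class{HeightMap}.
#' @param path destination file.
#' @param format \code{"tiff"}, \code{"csv"} or \code{"png16"}; inferred from
#'   the extension by default.
#' @return the path, invisibly.
#' @export
writeHeightMap <- function(h, path, format = .formatFromPath(path)) {
  stopifnot(methods::is(h, "HeightMap"))
  format <- match.arg(format, c("tiff", "csv", "png16"))
  ok <- tryCatch({
    switch(format,
      tiff = writeTIFF32(h@values, path),
      csv = utils::write.table(format(h@values, digits = 17L, scientific = TRUE,
                                      trim = TRUE),
                               path, sep = ",", row.names = FALSE,
                               col.names = FALSE, quote = FALSE),
      png16 = writePNG16(h@values, path))
    TRUE
  }, error = function(e) psStop("ps_io_error",
       sprintf("cannot write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' @rdname normalizeMap
#' @export
setMethod("normalizeMap", "HeightMap", function(h) {
  if (h@normState != "raw")
    psStop("ps_state_error", "height map is already normalized")
  v <- h@values
  lo <- min(v)
  hi <- max(v)
  if (hi > lo) {
    out <- (v - lo) / (hi - lo)
    pars <- c(lo, hi)
  } else {
    out <- array(0, dim(v))
    dim(out) <- dim(v)
    pars <- c(lo, lo + 1)
  }
  HeightMap(out, pixelSize = h@pixelSize, normState = "unit_normalized",
            normParams = pars)
})

#' @rdname denormalizeMap
#' @export
setMethod("denormalizeMap", "HeightMap", function(h) {
  if (h@normState != "unit_normalized")
    psStop("ps_state_error", "height map is not normalized")
  p <- h@normParams
  HeightMap(h@values * (p[2L] - p[1L]) + p[1L], pixelSize = h@pixelSize)
})

#' Read a line mask from a mask raster file
#'
#' Accepts 8-bit PNG (white = scanned) or CSV of 0/1. Every row must be
#' constant; the row-wise keep vector is returned as a
#' \linkS4class{LineMask} with pattern \code{"manual"}.
#'
#' @param path mask file.
#' @return a \linkS4class{LineMask}.
#' @export
readLineMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    round(x)
  } else {
    x <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(x) <- NULL
    x
  }
  rowconst <- apply(v, 1L, function(r) length(unique(r)) == 1L)
  if (!all(rowconst))
    psStop("ps_validation_error", "mask rows are not constant; not a line mask")
  keep <- v[, 1L] > 0.5
  methods::new("LineMask", keep = keep, fraction = mean(!keep),
               pattern = "manual", maxConsecutive = Inf, seed = NA_real_)
}

#' Write a line mask as an 8-bit PNG (255 = scanned) or CSV raster
#'
#' @param lm a \linkS4class{LineMask}.
#' @param path destination (.png or .csv).
#' @param n number of columns for the raster expansion.
#' @return the path, invisibly.
#' @export
writeLineMask <- function(lm, path, n) {
  mr <- expandMask(lm, n)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mr@values, path)
  } else {
    utils::write.table(mr@values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
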