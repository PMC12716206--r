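# Minimal 32-bit float grayscale TIFF writer (little-endian, single strip,
# uncompressed). The tiff package reads IEEE-float TIFFs natively but its
# writer only stores [0, 1]-clamped integer samples, which would destroy raw
# micrometre heights; archival export therefore assembles the float TIFF
# directly. writeBin(size = 4) performs the double -> float32 conversion.

.tiffShort <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
.tiffLong <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                  endian = "little")

.tiffEntry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
  val <- if (type == 3L) c(.tiffShort(value), as.raw(c(0, 0))) else .tiffLong(value)
  c(.tiffShort(tag), .tiffShort(type), .tiffLong(count), val)
}

#' Write a matrix as a 32-bit float grayscale TIFF
#'
#' Values are stored as IEEE single-precision floats without rescaling, so
#' any height range round-trips exactly at float32 precision.
#'
#' @param m numeric matrix (rows = scan lines).
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writeTIFF32 <- function(m, path) {
  h <- nrow(m)
  w <- ncol(m)
  dataBytes <- 4L * h * w
  # layout: 8-byte header, image data, then the IFD
  dataOffset <- 8L
  ifdOffset <- dataOffset + dataBytes
  entries <- list(
    .tiffEntry(256L, 4L, 1L, w),           # ImageWidth
    .tiffEntry(257L, 4L, 1L, h),           # ImageLength
    .tiffEntry(258L, 3L, 1L, 32L),         # BitsPerSample
    .tiffEntry(259L, 3L, 1L, 1L),          # Compression: none
    .tiffEntry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
    .tiffEntry(273L, 4L, 1L, dataOffset),  # StripOffsets
    .tiffEntry(277L, 3L, 1L, 1L),          # SamplesPerPixel
    .tiffEntry(278L, 4L, 1L, h),           # RowsPerStrip
    .tiffEntry(279L, 4L, 1L, dataBytes),   # StripByteCounts
    .tiffEntry(339L, 3L, 1L, 3L))          # SampleFormat: IEEE float
  header <- c(charToRaw("II"), .tiffShort(42L), .tiffLong(ifdOffset))
  ifd <- c(.tiffShort(length(entries)), do.call(c, entries), .tiffLong(0L))
  # pixel data row-major (TIFF scanlines)
  px <- writeBin(as.numeric(t(m)), raw(), size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, px, ifd), con)
  invisible(path)
}
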