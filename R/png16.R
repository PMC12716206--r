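# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit natively
# but only writes 8-bit, so the three required chunks (IHDR, IDAT, IEND) are
# assembled here directly; IDAT uses zlib deflate via memCompress and each
# scanline uses filter type 0.

# 32-bit XOR on doubles (R integers are signed 32-bit)
.xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(as.integer(al), as.integer(bl)) +
    65536 * bitwXor(as.integer(ah), as.integer(bh))
}

.crcTable <- local({
  tab <- numeric(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) c <- if (c %% 2 == 1) .xor32(3988292384, floor(c / 2)) else floor(c / 2)
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  c <- 4294967295
  for (x in as.integer(bytes)) {
    c <- .xor32(.crcTable[(.xor32(c, x) %% 256) + 1L], floor(c / 256))
  }
  .xor32(c, 4294967295)
}

.u32be <- function(x) {
  as.raw(c(floor(x / 2^24) %% 256, floor(x / 2^16) %% 256,
           floor(x / 2^8) %% 256, x %% 256))
}

.pngChunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32be(length(data)), td, .u32be(.crc32(td)))
}

#' Write a matrix as a 16-bit grayscale PNG
#'
#' Values are clipped to [0, 1] and quantized to 65535 levels, so the
#' round-trip error through [readHeightMap()] is at most 1/(2^16 - 1).
#'
#' @param m numeric matrix with values in [0, 1].
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writePNG16 <- function(m, path) {
  h <- nrow(m)
  w <- ncol(m)
  v <- round(pmin(pmax(m, 0), 1) * 65535)
  # scanlines: filter byte 0 followed by big-endian 16-bit samples
  dat <- raw(h * (1L + 2L * w))
  pos <- 1L
  for (r in seq_len(h)) {
    row <- v[r, ]
    dat[(pos + 1L):(pos + 2L * w)] <-
      as.raw(as.vector(rbind(floor(row / 256), row %% 256)))
    pos <- pos + 1L + 2L * w
  }
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .pngChunk("IHDR", ihdr),
           .pngChunk("IDAT", memCompress(dat, type = "gzip")),
           .pngChunk("IEND", raw(0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
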