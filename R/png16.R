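# Minimal 16-bit grayscale PNG encoder.
#
# png::readPNG reads 16-bit grayscale PNGs losslessly (values / 65535), but
# png::writePNG quantizes to 8 bits.  Processed CEM images use the full
# 16-bit range, so writing goes through this encoder: IHDR (bit depth 16,
# colour type 0) + one zlib-compressed IDAT with filter type 0 per row.

# CRC32 of a raw vector, recovered from the trailer of a gzip stream
# (RFC 1952: ...CRC32, ISIZE, both little-endian).
crc32_raw <- function(bytes) {
  f <- tempfile(fileext = ".gz")
  on.exit(unlink(f), add = TRUE)
  con <- gzfile(f, "wb")
  writeBin(bytes, con)
  close(con)
  sz <- file.size(f)
  con <- file(f, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, sz - 8)
  rev(readBin(con, "raw", n = 4L))  # big-endian for PNG
}

uint32_be <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data = raw()) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, crc32_raw(body))
}

# pixels: integer-valued matrix [row, col] in 0..65535.
write_png16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  v <- as.integer(round(pixels))
  if (anyNA(v) || any(v < 0L) || any(v > 65535L)) {
    abort("16-bit PNG write requires finite values in [0, 65535]")
  }
  h <- nrow(pixels); w <- ncol(pixels)
  m <- matrix(v, h, w)
  # big-endian uint16 scanlines, row-major, each preceded by filter byte 0
  scan <- matrix(as.raw(0L), nrow = 1L + 2L * w, ncol = h)
  rowdat <- t(m)                        # column j of t(m) = image row j
  scan[seq(2L, 2L * w, by = 2L), ] <- as.raw(rowdat %/% 256L)
  scan[seq(3L, 2L * w + 1L, by = 2L), ] <- as.raw(rowdat %% 256L)
  idat <- memCompress(as.vector(scan), type = "gzip")  # zlib stream
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  out <- c(sig,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}
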