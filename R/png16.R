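#' Write / read a height map as 16-bit grayscale PNG
#'
#' Heights are stored at 0.1 mm quantization: the stored sample is
#' `round(height_mm * 10) + 1`, with 0 reserved for invalid pixels, so a
#' valid height of 0 mm encodes as 1. Heights outside the encodable range
#' (below -0.05 mm or above 6553.4 mm) raise an error naming the offending
#' value. `read_height_png()` inverts the encoding bit-exactly.
#'
#' @param field a `height_field` (see [disparity_to_height()]).
#' @param path output/input file path.
#' @return `write_height_png()` returns `path` invisibly;
#'   `read_height_png()` returns a `height_field`.
#' @export
write_height_png <- function(field, path) {
  stopifnot(inherits(field, "height_field"))
  h <- field$heights_mm
  code <- round(h * 10) + 1
  code[!field$valid] <- 0
  bad <- field$valid & (code < 1 | code > 65535)
  if (any(bad)) {
    v <- h[which(bad)[1]]
    tv_data_error(sprintf(
      "write_height_png: height %.2f mm outside the encodable range [-0.05, 6553.4]", v))
  }
  png16_write_gray(matrix(as.integer(code), nrow(h), ncol(h)), path)
  invisible(path)
}

#' @rdname write_height_png
#' @export
read_height_png <- function(path) {
  if (!file.exists(path)) tv_data_error(paste0("cannot read height map: ", path))
  px <- png::readPNG(path)
  if (length(dim(px)) != 2L)
    tv_data_error("read_height_png: expected a single-channel grayscale PNG")
  code <- round(px * 65535)
  valid <- code >= 1
  h <- (code - 1) / 10
  h[!valid] <- NA_real_
  structure(list(heights_mm = h, valid = valid), class = "height_field")
}

# --- minimal 16-bit grayscale PNG encoder -------------------------------
# Samples are uint16 big-endian, one per pixel, scanlines prefixed with
# filter byte 0; the IDAT payload is a zlib stream (memCompress gives the
# RFC 1950 wrapper). Chunk CRCs via the compiled CRC-32.

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32_raw(body)))
}

png16_write_gray <- function(code, path) {
  stopifnot(is.matrix(code))
  nr <- nrow(code); nc <- ncol(code)
  # row-major scanlines: top row first, filter byte 0, 2 bytes per sample
  samples <- t(code)                      # column of `samples` = image row
  hi <- as.raw(samples %/% 256L)
  lo <- as.raw(samples %% 256L)
  inter <- as.vector(rbind(hi, lo))      # big-endian byte pairs
  dim(inter) <- c(2L * nc, nr)
  raw_rows <- rbind(matrix(as.raw(0L), 1L, nr), inter)
  ihdr <- c(u32be(nc), u32be(nr), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(as.vector(raw_rows), type = "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}
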