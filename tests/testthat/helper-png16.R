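# Minimal 16-bit grayscale PNG writer, used only to generate reader
# fixtures at test time (the installed PNG writer is 8-bit only). Chunk
# CRC32 is computed in plain R; the IDAT payload comes from base R's
# memCompress, whose "gzip" type emits the zlib (RFC 1950) stream PNG
# requires.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed int
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(crc32_table[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

uint32_be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(uint32_be(length(data)), body, uint32_be(if (crc < 0) crc + 2^32 else crc))
}

zlib_wrap <- function(bytes) memCompress(bytes, type = "gzip")

# values: integer matrix in 0..65535
write_png16 <- function(values, path) {
  nr <- nrow(values); nc <- ncol(values)
  rows <- lapply(seq_len(nr), function(r) {
    v <- as.integer(values[r, ])
    as.raw(c(0L, rbind(v %/% 256L, v %% 256L)))  # filter byte 0 + big-endian
  })
  raw_data <- do.call(c, rows)
  ihdr <- c(uint32_be(nc), uint32_be(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))      # 16-bit grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib_wrap(raw_data)), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
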