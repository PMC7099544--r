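#' Read a 2D grayscale image
#'
#' Supported formats: 8/16-bit PNG (values rescaled back to integer counts
#' using the file's bit depth), TIFF (integer or 32-bit float, read
#' unscaled), and whitespace-delimited plain-text matrices. Multi-channel
#' inputs are converted to luminance with the fixed Rec. 601 weights
#' (0.299, 0.587, 0.114).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`,
#'   anything else is parsed as a text matrix).
#' @return numeric matrix (single-channel float).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    to_gray(raw) * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    to_gray(tiff::readTIFF(path, as.is = FALSE))
  } else {
    m <- tryCatch(as.matrix(utils::read.table(path)),
                  error = function(e) stop(sprintf(
                    "cannot parse %s as a text matrix: %s", path,
                    conditionMessage(e)), call. = FALSE))
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  if (!all(is.finite(img)))
    stop(sprintf("image %s contains non-finite values", path), call. = FALSE)
  attributes(img) <- list(dim = dim(img))
  img
}

#' @keywords internal
to_gray <- function(x) {
  if (length(dim(x)) == 2L) return(x)
  nch <- dim(x)[3]
  if (nch == 1L) return(x[, , 1])
  # Rec. 601 luminance; an alpha channel, if present, is ignored
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Write a 2D image
#'
#' `format = "tiff32"` stores the raw float values in an uncompressed
#' 32-bit float grayscale TIFF (exact round trip through [read_image()] at
#' single precision); `"png8"` min-max normalises to 8 bits (display
#' export; raw values are not preserved); `"text"` writes a
#' whitespace-delimited matrix at full double precision.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param format one of `"tiff32"`, `"png8"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path,
                        format = c("tiff32", "png8", "text")) {
  assert_image(image)
  format <- match.arg(format)
  switch(format,
    tiff32 = write_tiff32(image, path),
    png8 = png::writePNG(minmax01(image), path),
    text = {
      con <- file(path, "w")
      on.exit(close(con))
      utils::write.table(format(image, digits = 17, scientific = TRUE,
                                trim = TRUE),
                         con, row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    })
  invisible(path)
}

# Minimal single-strip little-endian 32-bit IEEE float grayscale TIFF.
# Assembled here because the available TIFF writer clamps float samples to
# [0, 1]; signed/unbounded maps (ICF, difference images) need raw storage.
#' @keywords internal
write_tiff32 <- function(image, path) {
  nr <- nrow(image); nc <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")            # first IFD offset
  ntags <- 8L
  data_off <- 8L + 2L + ntags * 12L + 4L
  writeBin(ntags, con, size = 2, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  tag(256, 4, 1, nc)                # ImageWidth
  tag(257, 4, 1, nr)                # ImageLength
  tag(258, 3, 1, 32)                # BitsPerSample
  tag(262, 3, 1, 1)                 # PhotometricInterpretation: BlackIsZero
  tag(273, 4, 1, data_off)          # StripOffsets
  tag(278, 4, 1, nr)                # RowsPerStrip
  tag(279, 4, 1, 4 * nr * nc)       # StripByteCounts
  tag(339, 3, 1, 3)                 # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")            # no next IFD
  writeBin(as.vector(t(image)), con, size = 4, endian = "little")
  invisible(path)
}
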