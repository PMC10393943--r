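#' Minimal baseline TIFF reader and writer
#'
#' Single-channel grayscale baseline TIFF support (uncompressed, strip-based,
#' one sample per pixel). This covers every image artifact the package
#' produces and consumes: per-marker intensity images (32-bit float),
#' segmentation masks and label maps (32-bit unsigned integer). No TIFF
#' package is assumed; the codec is self-contained.
#'
#' @name tiff_io
#' @keywords internal
NULL

.TIFF_TYPES <- list(
  float32 = list(bits = 32L, format = 3L, size = 4L),
  uint32  = list(bits = 32L, format = 1L, size = 4L),
  uint16  = list(bits = 16L, format = 1L, size = 2L),
  uint8   = list(bits = 8L,  format = 1L, size = 1L)
)

#' Write a matrix as a single-channel grayscale TIFF
#'
#' @param x numeric matrix (rows = image rows, top row first).
#' @param path output file path.
#' @param type pixel type: `"float32"` (intensities), `"uint32"`, `"uint16"`
#'   or `"uint8"` (labels).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, type = c("float32", "uint32", "uint16", "uint8")) {
  type <- match.arg(type)
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  tt <- .TIFF_TYPES[[type]]
  if (tt$format == 1L) {
    v <- as.vector(t(x))
    if (any(v < 0)) stop("negative values cannot be stored as unsigned integers", call. = FALSE)
    cap <- if (type == "uint8") 255 else if (type == "uint16") 65535 else 2147483647
    if (any(v > cap)) {
      stop(sprintf("label ids exceed the capacity of %s (max %s)", type,
                   format(cap, scientific = FALSE)), call. = FALSE)
    }
  }
  h <- nrow(x); w <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))

  n_entries <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L

  # header: little-endian, magic 42, first IFD at byte 8
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")

  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L) { # SHORT: value in first two bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256L, 4L, 1L, w)                       # ImageWidth
  entry(257L, 4L, 1L, h)                       # ImageLength
  entry(258L, 3L, 1L, tt$bits)                 # BitsPerSample
  entry(259L, 3L, 1L, 1L)                      # Compression: none
  entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)             # StripOffsets
  entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
  entry(278L, 4L, 1L, h)                       # RowsPerStrip
  entry(279L, 4L, 1L, h * w * tt$size)         # StripByteCounts
  entry(339L, 3L, 1L, tt$format)               # SampleFormat
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD

  v <- as.vector(t(x))  # TIFF strips are row-major
  if (type == "float32") {
    writeBin(as.double(v), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(v)), con, size = tt$size, endian = "little")
  }
  invisible(path)
}

#' Read a single-channel grayscale TIFF into a matrix
#'
#' Supports uncompressed, single-sample baseline TIFFs (either byte order;
#' 8/16/32-bit unsigned integer, 32/64-bit float).
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  con <- rawConnection(raw_all, "rb")
  on.exit(close(con))

  order_tag <- readChar(con, 2, useBytes = TRUE)
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop(sprintf("not a TIFF file: %s", path), call. = FALSE)
  magic <- readBin(con, "integer", size = 2, endian = endian)
  if (magic != 42L) stop(sprintf("not a TIFF file: %s", path), call. = FALSE)
  ifd_offset <- readBin(con, "integer", size = 4, endian = endian)

  seek(con, ifd_offset)
  n_entries <- readBin(con, "integer", size = 2, endian = endian)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  for (e in seq_len(n_entries)) {
    tag <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
    typ <- readBin(con, "integer", size = 2, endian = endian)
    count <- readBin(con, "integer", size = 4, endian = endian)
    value_bytes <- readBin(con, "raw", n = 4)
    sz <- type_size[[as.character(typ)]]
    read_vals <- function(r) {
      vcon <- rawConnection(r, "rb")
      on.exit(close(vcon))
      readBin(vcon, "integer", n = count, size = sz, endian = endian,
              signed = sz >= 4L)
    }
    if (sz * count <= 4L) {
      vals <- read_vals(value_bytes)
    } else {
      vcon <- rawConnection(value_bytes, "rb")
      off <- readBin(vcon, "integer", size = 4, endian = endian)
      close(vcon)
      vals <- {
        pos <- seek(con)       # remember IFD position
        seek(con, off)
        v <- readBin(con, "integer", n = count, size = sz, endian = endian,
                     signed = sz >= 4L)
        seek(con, pos)
        v
      }
    }
    tags[[as.character(tag)]] <- vals
  }

  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop(sprintf("TIFF tag %d missing in %s", tag, path), call. = FALSE)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 1L)
  compression <- need(259L, 1L)
  if (compression != 1L) stop("compressed TIFFs are not supported", call. = FALSE)
  spp <- need(277L, 1L)
  if (spp != 1L || length(bits) != 1L)
    stop("only single-sample grayscale TIFFs are supported", call. = FALSE)
  fmt <- need(339L, 1L)
  offsets <- need(273L)
  rows_per_strip <- need(278L, h)
  counts <- need(279L)

  px_size <- bits %/% 8L
  values <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n_px <- counts[s] %/% px_size
    strip <- if (fmt == 3L) {
      readBin(con, "numeric", n = n_px, size = px_size, endian = endian)
    } else {
      v <- readBin(con, "integer", n = n_px, size = px_size, endian = endian,
                   signed = px_size >= 4L)
      if (px_size == 4L && any(v < 0))
        stop("unsigned 32-bit values above 2^31-1 are not supported", call. = FALSE)
      as.numeric(v)
    }
    values <- c(values, strip)
  }
  if (length(values) != h * w)
    stop(sprintf("TIFF pixel count mismatch in %s", path), call. = FALSE)
  matrix(values, nrow = h, ncol = w, byrow = TRUE)
}
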