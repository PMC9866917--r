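# Minimal baseline TIFF codec (8-bit, uncompressed, RGB or grayscale).
# The grading image ships no TIFF package for R, and the pipeline only needs
# plain 8-bit frames, so a small reader/writer is carried here. Anything
# beyond baseline uncompressed 8-bit is rejected explicitly.

.tiff_read_header <- function(con) {
  bom <- readBin(con, "raw", 2L)
  if (identical(bom, as.raw(c(0x49, 0x49)))) endian <- "little"
  else if (identical(bom, as.raw(c(0x4d, 0x4d)))) endian <- "big"
  else stop("not a TIFF file (bad byte-order mark)")
  magic <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number)")
  offset <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  list(endian = endian, ifd_offset = offset)
}

.tiff_read_entry_values <- function(con, type, count, raw4, endian) {
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(size)) return(NULL)
  total <- size * count
  if (total <= 4L) {
    vals_raw <- raw4[seq_len(total)]
  } else {
    off <- readBin(raw4, "integer", 1L, size = 4L, endian = endian)
    pos <- seek(con)
    seek(con, off)
    vals_raw <- readBin(con, "raw", total)
    seek(con, pos)
  }
  readBin(vals_raw, "integer", count, size = size,
          signed = size == 4L, endian = endian)
}

read_tiff_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .tiff_read_header(con)
  endian <- hdr$endian
  seek(con, hdr$ifd_offset)
  n_entries <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (k in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    raw4 <- readBin(con, "raw", 4L)
    tags[[as.character(tag)]] <- .tiff_read_entry_values(con, type, count, raw4, endian)
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  width <- g(256); height <- g(257)
  if (is.null(width) || is.null(height)) stop("TIFF missing dimensions: ", path)
  bits <- g(258, 1L)
  if (any(bits != 8L))
    stop(sprintf("unsupported bit depth (%s) in TIFF '%s': only 8-bit is supported",
                 paste(unique(bits), collapse = "/"), path))
  compression <- g(259, 1L)
  if (compression != 1L)
    stop("unsupported TIFF compression in '", path, "': only uncompressed is supported")
  spp <- g(277, 1L)
  if (!spp %in% c(1L, 3L))
    stop("unsupported TIFF samples-per-pixel (", spp, ") in '", path, "'")
  planar <- g(284, 1L)
  if (planar != 1L) stop("unsupported TIFF planar configuration in '", path, "'")
  offsets <- g(273); counts <- g(279)
  if (is.null(offsets)) stop("TIFF missing strip offsets: ", path)
  if (is.null(counts)) counts <- rep(height * width * spp / length(offsets), length(offsets))
  data <- raw(0)
  for (k in seq_along(offsets)) {
    seek(con, offsets[k])
    data <- c(data, readBin(con, "raw", counts[k]))
  }
  px <- as.integer(data)
  if (length(px) < height * width * spp) stop("truncated TIFF pixel data: ", path)
  px <- px[seq_len(height * width * spp)]
  if (spp == 1L) {
    m <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
    arr <- array(rep(m, 3L), dim = c(height, width, 3L))
  } else {
    # interleaved RGBRGB..., row-major
    arr <- array(0L, dim = c(height, width, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(px[seq(ch, length(px), by = 3L)],
                            nrow = height, ncol = width, byrow = TRUE)
  }
  rgb_image(arr)
}

write_tiff_image <- function(img, path) {
  assert_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  # interleaved row-major pixel data
  px <- integer(h * w * 3L)
  for (ch in 1:3) px[seq(ch, length(px), by = 3L)] <- as.integer(t(img[, , ch]))
  data_offset <- 8L
  n_tags <- 8L
  ifd_offset <- data_offset + length(px)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)                       # little-endian
  writeBin(c(42L), con, size = 2L, endian = "little")
  writeBin(ifd_offset, con, size = 4L, endian = "little")
  writeBin(as.raw(px), con)
  wr_tag <- function(tag, type, count, value) {
    writeBin(tag, con, size = 2L, endian = "little")
    writeBin(type, con, size = 2L, endian = "little")
    writeBin(count, con, size = 4L, endian = "little")
    if (type == 3L && count <= 2L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      if (count == 1L) writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2L, endian = "little")
  wr_tag(256L, 4L, 1L, w)                                    # ImageWidth
  wr_tag(257L, 4L, 1L, h)                                    # ImageLength
  wr_tag(258L, 3L, 3L, ifd_offset + 2L + n_tags * 12L + 4L)  # BitsPerSample ptr
  wr_tag(259L, 3L, 1L, 1L)                                   # no compression
  wr_tag(262L, 3L, 1L, 2L)                                   # RGB
  wr_tag(273L, 4L, 1L, data_offset)                          # StripOffsets
  wr_tag(277L, 3L, 1L, 3L)                                   # SamplesPerPixel
  wr_tag(279L, 4L, 1L, length(px))                           # StripByteCounts
  writeBin(0L, con, size = 4L, endian = "little")            # next IFD
  writeBin(rep(8L, 3L), con, size = 2L, endian = "little")   # bits values
  invisible(path)
}
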