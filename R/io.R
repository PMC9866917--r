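#' Read an 8-bit RGB microscopy image
#'
#' Supported containers: PNG, baseline uncompressed TIFF, and JPEG (accepted
#' with a lossy-format warning). Grayscale sources are replicated to three
#' channels and any alpha channel is dropped. Only 8-bit channel depth is
#' supported: 16-bit sources raise an error rather than being rescaled
#' silently.
#'
#' @param path path to a `.png`, `.tif`/`.tiff` or `.jpg`/`.jpeg` file.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      .check_png_depth(path)
      png::readPNG(path)
    },
    tif = , tiff = return(read_tiff_image(path)),
    jpg = , jpeg = {
      warning("JPEG input '", path, "' is lossy; prefer PNG or TIFF")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '.", ext, "' for '", path,
         "' (expected PNG, TIFF or JPEG)")
  )
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] == 2L) arr <- array(rep(arr[, , 1], 3L), dim = c(dim(arr)[1:2], 3L))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  rgb_image(round(arr * 255))
}

# PNG stores the bit depth at byte 25 (after the 8-byte signature and the
# IHDR length/type); reject anything but 8 before decoding.
.check_png_depth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  if (length(hdr) < 26L || !identical(hdr[1:8],
      as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("corrupt or non-PNG file: '", path, "'")
  depth <- as.integer(hdr[25])
  if (depth != 8L)
    stop(sprintf("unsupported bit depth (%d) in PNG '%s': only 8-bit is supported",
                 depth, path))
  invisible(TRUE)
}

#' Write an 8-bit RGB image
#'
#' @param img an [rgb_image()].
#' @param path output path; format chosen by extension (`.png` or
#'   `.tif`/`.tiff`). PNG and uncompressed TIFF round-trip bit-exactly
#'   through [read_image()].
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(unclass(img) / 255, path),
    tif = , tiff = write_tiff_image(img, path),
    stop("unsupported output format '.", ext, "' (expected PNG or TIFF)")
  )
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop("write_mask: mask must be a matrix")
  m <- matrix(as.numeric(as.logical(mask)), nrow = nrow(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path a single-channel PNG with values 0/255.
#' @return logical matrix, TRUE = foreground.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file '", path, "'")
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Serialize a provenance record to JSON
#'
#' @param prov a [provenance_record()].
#' @param path output `.json` path.
#' @export
write_provenance <- function(prov, path) {
  stopifnot(inherits(prov, "provenance_record"))
  out <- unclass(prov)
  if (is.infinite(out$probe_psnr_db)) out$probe_psnr_db <- "Inf"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
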