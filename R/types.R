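#' @useDynLib ihcsubtype, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct an 8-bit RGB image
#'
#' The unit of every pipeline stage: an integer array of dimension
#' height x width x 3 with values in \[0, 255\], row-major with origin at the
#' top-left and (row, col) indexing. Channel order is always R, G, B
#' regardless of the source library.
#'
#' @param x numeric or integer array, H x W x 3, values in \[0, 255\];
#'   an H x W matrix is replicated to three identical channels.
#' @return an object of class `rgb_image` (integer array).
#' @export
rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("rgb_image: expected an H x W x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("rgb_image: height and width must be >= 1")
  if (anyNA(x)) stop("rgb_image: NA pixel values")
  if (min(x) < 0 || max(x) > 255)
    stop("rgb_image: pixel values must lie in [0, 255]")
  if (is.double(x)) {
    if (any(x != floor(x))) stop("rgb_image: pixel values must be integers")
    storage.mode(x) <- "integer"
  }
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit RGB, mean luma %.1f>\n",
              d[1], d[2], average_brightness(x)))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

assert_rgb <- function(x, arg = "img") {
  if (!is_rgb_image(x)) stop(sprintf("%s must be an rgb_image", arg))
  invisible(x)
}

assert_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("image dimension mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Canonical biomarker kinds
#'
#' The four immunohistochemical biomarkers used for subtype diagnosis.
#' @export
BIOMARKERS <- c("PR", "ER", "HER2", "KI67")

.biomarker_aliases <- c(
  pr = "PR", progesterone = "PR",
  er = "ER", estrogen = "ER",
  her2 = "HER2", "her2/neu" = "HER2", her2neu = "HER2", oncoprotein = "HER2",
  ki67 = "KI67", "ki-67" = "KI67", ki_67 = "KI67",
  proliferation = "KI67", "cell proliferation biomarker" = "KI67"
)

#' Normalize a biomarker name
#'
#' Case-insensitive; accepts common aliases ("er", "estrogen",
#' "oncoprotein", "ki-67", ...).
#' @param x character scalar.
#' @return one of `"PR"`, `"ER"`, `"HER2"`, `"KI67"`.
#' @export
biomarker <- function(x) {
  if (length(x) != 1L || !is.character(x)) stop("biomarker: expected one string")
  key <- tolower(trimws(x))
  if (toupper(key) %in% BIOMARKERS) return(toupper(key))
  out <- unname(.biomarker_aliases[key])
  if (is.na(out))
    stop(sprintf("unknown biomarker '%s' (expected one of %s or an alias)",
                 x, paste(BIOMARKERS, collapse = ", ")))
  out
}

#' Canonical tumor grades
#' @export
GRADES <- c("G1", "G2", "G3")

#' Normalize a histological grade
#' @param x `"G1"`/`"G2"`/`"G3"` (case-insensitive, "1"/"2"/"3" accepted)
#'   or NULL.
#' @return normalized grade string, or NULL.
#' @export
grade <- function(x) .normalize_grade(x)

.normalize_grade <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) != 1L) stop("grade: expected one value")
  key <- toupper(trimws(as.character(x)))
  if (key %in% c("1", "2", "3")) key <- paste0("G", key)
  if (!key %in% GRADES)
    stop(sprintf("unknown grade '%s' (expected G1, G2 or G3)", x))
  key
}

#' Provenance record of a preprocessing run
#'
#' Records the adaptive decisions taken by [preprocess()]: the probe PSNR,
#' the median window it selected, the mean brightness of the filtered image,
#' the gain it selected, and digests of every intermediate stage.
#'
#' @param probe_psnr_db PSNR (dB) between the 3x3 probe-filtered image and
#'   the input; `Inf` for a noise-free input.
#' @param selected_window median filter window side, 3 or 5.
#' @param mean_brightness_y mean luma of the filtered image, in \[0, 255\].
#' @param selected_alpha brightness gain, one of 20, 12, 8, 6, 4.
#' @param stage_checksums named character vector of digests for stages
#'   I, II, III, IIII.
#' @return object of class `provenance_record`.
#' @export
provenance_record <- function(probe_psnr_db, selected_window,
                              mean_brightness_y, selected_alpha,
                              stage_checksums) {
  if (!selected_window %in% c(3L, 5L))
    stop("selected_window must be 3 or 5")
  if (!selected_alpha %in% c(4L, 6L, 8L, 12L, 20L))
    stop("selected_alpha must be one of 4, 6, 8, 12, 20")
  stopifnot(is.character(stage_checksums),
            all(c("I", "II", "III", "IIII") %in% names(stage_checksums)))
  structure(list(probe_psnr_db = probe_psnr_db,
                 selected_window = as.integer(selected_window),
                 mean_brightness_y = mean_brightness_y,
                 selected_alpha = as.integer(selected_alpha),
                 stage_checksums = as.list(stage_checksums)),
            class = "provenance_record")
}

#' @export
print.provenance_record <- function(x, ...) {
  cat(sprintf(
    "<provenance: probe PSNR %.2f dB -> window %d; Y = %.2f -> alpha %d>\n",
    x$probe_psnr_db, x$selected_window, x$mean_brightness_y, x$selected_alpha))
  invisible(x)
}

image_checksum <- function(img) digest::digest(unclass(img))

#' Per-pixel luma of an image
#'
#' The weighted brightness 0.299 R + 0.587 G + 0.114 B used throughout the
#' pipeline (brightness correction, threshold bands, intensity scoring).
#'
#' @param img an [rgb_image()].
#' @return numeric H x W matrix in \[0, 255\].
#' @export
luma <- function(img) {
  assert_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
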