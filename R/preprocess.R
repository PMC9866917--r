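# Adaptive preprocessing: a 3x3 median probe estimates the impulse-noise
# level via PSNR, which picks the working median window; the filtered
# image's mean luma then picks a multiplicative brightness gain.

#' Mean squared error between two images
#'
#' Mean of squared per-pixel differences, averaged jointly over all pixels
#' and all three channels.
#'
#' @param a,b [rgb_image()]s of identical dimensions.
#' @return non-negative scalar (squared grayscale levels).
#' @export
compute_mse <- function(a, b) {
  assert_rgb(a, "a"); assert_rgb(b, "b")
  assert_same_dim(a, b)
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(255^2 / MSE)` in decibels; `Inf` for identical images.
#'
#' @inheritParams compute_mse
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
compute_psnr <- function(a, b) {
  mse <- compute_mse(a, b)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Select the median filter window from a probe PSNR
#'
#' Noisy images (probe PSNR <= 20 dB) get the aggressive 5x5 window,
#' cleaner ones the 3x3 window.
#'
#' @param psnr_db probe PSNR in dB (non-negative or `Inf`).
#' @return window side, 3L or 5L.
#' @export
select_filter_window <- function(psnr_db) {
  if (!is.numeric(psnr_db) || length(psnr_db) != 1L || is.na(psnr_db) || psnr_db < 0)
    stop("select_filter_window: psnr_db must be a non-negative scalar")
  if (psnr_db <= 20) 5L else 3L
}

#' Per-channel median filter
#'
#' Square window, reflect (half-sample symmetric) border padding.
#'
#' @param img an [rgb_image()].
#' @param window odd window side >= 3.
#' @return filtered [rgb_image()].
#' @export
median_filter <- function(img, window = 3L) {
  assert_rgb(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("median_filter: window must be an odd integer >= 3")
  out <- unclass(img)
  for (ch in 1:3) out[, , ch] <- cpp_median_filter(img[, , ch], window)
  rgb_image(out)
}

#' Mean brightness (luma) of an image
#'
#' Mean over all pixels of 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img an [rgb_image()].
#' @return scalar in \[0, 255\].
#' @export
average_brightness <- function(img) mean(luma(img))

#' Select the brightness gain from mean brightness
#'
#' The published step table: darker frames receive a larger gain.
#' gain 20 for Y <= 10, 12 for (10, 40], 8 for (40, 150], 6 for (150, 200],
#' 4 for Y > 200.
#'
#' @param y mean brightness in \[0, 255\].
#' @param table optional replacement bin table (columns y_min, y_max, alpha;
#'   upper bounds inclusive).
#' @return integer gain.
#' @export
select_alpha <- function(y, table = NULL) {
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y < 0 || y > 255)
    stop("select_alpha: y must lie in [0, 255]")
  if (is.null(table)) table <- ihc_default_config()$alpha_table
  hit <- which(y > table$y_min & y <= table$y_max)
  if (length(hit) != 1L) stop("select_alpha: gain table does not partition [0, 255]")
  as.integer(table$alpha[hit])
}

#' Multiply an image by a brightness gain
#'
#' Saturating multiplication: each channel value is multiplied by `alpha`,
#' rounded half-up and clipped to \[0, 255\].
#'
#' @param img an [rgb_image()].
#' @param alpha positive gain.
#' @return amplified [rgb_image()].
#' @export
apply_gain <- function(img, alpha) {
  assert_rgb(img)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("apply_gain: alpha must be a positive scalar")
  x <- floor(as.numeric(img) * alpha + 0.5)
  rgb_image(array(pmin(pmax(x, 0), 255), dim = dim(img)))
}

#' Adaptive preprocessing chain
#'
#' Executes the full published chain on an input image I:
#' II = 3x3 probe median of I; the probe PSNR between II and I selects the
#' working window (5x5 iff PSNR <= 20 dB); III = working median of II;
#' the mean luma Y of III selects a gain alpha; IIII = alpha x III.
#'
#' @param img input [rgb_image()] (stage I).
#' @param config configuration list from [ihc_config()].
#' @return list with `image` (stage IIII), `provenance`
#'   (a [provenance_record()]) and `stages` (list of I, II, III).
#' @export
preprocess <- function(img, config = ihc_config()) {
  assert_rgb(img)
  II <- median_filter(img, config$probe_window)
  psnr <- compute_psnr(II, img)
  side <- .window_from_rule(psnr, config$window_rule)
  III <- median_filter(II, side)
  y <- average_brightness(III)
  alpha <- select_alpha(y, config$alpha_table)
  IIII <- apply_gain(III, alpha)
  prov <- provenance_record(
    probe_psnr_db = psnr, selected_window = side,
    mean_brightness_y = y, selected_alpha = alpha,
    stage_checksums = c(I = image_checksum(img), II = image_checksum(II),
                        III = image_checksum(III), IIII = image_checksum(IIII)))
  list(image = IIII, provenance = prov, stages = list(I = img, II = II, III = III))
}

.window_from_rule <- function(psnr_db, rule) {
  if (psnr_db < 0) stop("negative PSNR")
  hit <- which(psnr_db > rule$psnr_min & psnr_db <= rule$psnr_max)
  if (length(hit) != 1L) stop("window rule does not partition the PSNR axis")
  as.integer(rule$side[hit])
}
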