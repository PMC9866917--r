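# Biomarker-specific threshold band + marker-controlled watershed.
# The band proposes candidate positive pixels on luma; morphological
# opening, a distance transform, and watershed flooding on the Sobel
# gradient then split touching nuclei and discard debris.

#' Published per-biomarker segmentation thresholds
#'
#' PR (160, 180); ER (180, 210); HER2 (40, 230); KI67 (160, 180).
#'
#' @param biomarker biomarker name or alias (see [biomarker()]).
#' @param config configuration (the `thresholds` family may be overridden).
#' @return named numeric vector `c(lower, upper)` with attribute
#'   `biomarker`.
#' @export
select_thresholds <- function(biomarker, config = ihc_config()) {
  bm <- biomarker(biomarker)
  thr <- config$thresholds[[bm]]
  if (is.null(thr)) stop("no thresholds configured for biomarker ", bm)
  thr <- c(lower = unname(thr["lower"]), upper = unname(thr["upper"]))
  if (is.na(thr["lower"]) || is.na(thr["upper"]) ||
      thr["lower"] < 0 || thr["upper"] > 255 || thr["lower"] > thr["upper"])
    stop("invalid thresholds for ", bm, ": need 0 <= lower <= upper <= 255")
  attr(thr, "biomarker") <- bm
  thr
}

#' Threshold band on luma
#'
#' A pixel is candidate foreground iff its luma g satisfies
#' lower <= g <= upper (inclusive band).
#'
#' @param img an [rgb_image()].
#' @param thresholds `c(lower, upper)` from [select_thresholds()].
#' @return logical H x W matrix.
#' @export
threshold_band <- function(img, thresholds) {
  g <- luma(img)
  g >= thresholds[["lower"]] & g <= thresholds[["upper"]]
}

#' Marker-controlled watershed segmentation of a candidate mask
#'
#' Recipe: morphological opening of the candidate (3x3 cross element,
#' `open_iter` iterations); sure background = complement of a `dilate_iter`
#' dilation; distance transform of the opened mask; sure foreground =
#' distance > `dist_frac` x max distance; markers = 4-connected components
#' of the sure foreground; watershed flooding of the remaining unknown
#' pixels on the Sobel gradient of the image luma; ridge pixels count as
#' background; components smaller than `min_object_px` are removed.
#'
#' @param img an [rgb_image()] (supplies the gradient relief).
#' @param candidate logical candidate-foreground mask from
#'   [threshold_band()].
#' @param morphology list with `open_iter`, `dilate_iter`, `dist_frac`,
#'   `min_object_px`.
#' @param params_used optional record (thresholds etc.) echoed in the
#'   result.
#' @return `segmentation_result`: list with `foreground_mask`, `labels`
#'   (0 = background), `positive_area_sp`, `window_area_sw`, `n_objects`,
#'   `params_used`.
#' @export
watershed_segment <- function(img, candidate,
                              morphology = ihc_default_config()$morphology,
                              params_used = list()) {
  assert_rgb(img)
  if (!is.matrix(candidate) || !identical(dim(candidate), dim(img)[1:2]))
    stop("candidate mask dimensions must match the image")
  mode(candidate) <- "logical"
  sw <- prod(dim(candidate))
  params_used <- c(params_used, list(morphology = morphology))
  empty <- function() {
    structure(list(foreground_mask = matrix(FALSE, nrow(candidate), ncol(candidate)),
                   labels = matrix(0L, nrow(candidate), ncol(candidate)),
                   positive_area_sp = 0L, window_area_sw = sw,
                   n_objects = 0L, params_used = params_used),
              class = "segmentation_result")
  }
  if (!any(candidate)) return(empty())

  opened <- cpp_dilate(cpp_erode(candidate, morphology$open_iter),
                       morphology$open_iter)
  if (!any(opened)) return(empty())
  sure_bg_zone <- cpp_dilate(opened, morphology$dilate_iter)
  dist <- cpp_distance_transform(opened)
  sure_fg <- dist > morphology$dist_frac * max(dist)
  markers <- cpp_label4(sure_fg) + 1L          # objects get labels >= 2
  markers[!sure_bg_zone] <- 1L                 # background marker
  markers[sure_bg_zone & !sure_fg] <- 0L       # unknown: to be flooded
  ws <- cpp_watershed(cpp_sobel(luma(img)), markers)

  labels <- ws - 1L
  labels[labels < 0L] <- 0L                    # ridge and background
  counts <- tabulate(labels, nbins = max(labels, 1L))
  small <- which(counts > 0 & counts < morphology$min_object_px)
  if (length(small)) labels[labels %in% small] <- 0L
  keep <- which(tabulate(labels, nbins = max(labels, 1L)) > 0)
  relabel <- integer(max(labels, 1L))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  fg <- labels > 0L
  structure(list(foreground_mask = fg, labels = labels,
                 positive_area_sp = as.integer(sum(fg)),
                 window_area_sw = as.integer(sw),
                 n_objects = length(keep), params_used = params_used),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation: %d objects, Sp = %d / Sw = %d (deltaS = %.4f)>\n",
              x$n_objects, x$positive_area_sp, x$window_area_sw,
              x$positive_area_sp / x$window_area_sw))
  invisible(x)
}

#' Segment a biomarker image
#'
#' Composes [select_thresholds()], [threshold_band()] and
#' [watershed_segment()]. The image is segmented as given; in the full
#' pipeline ([compute_indicator_set()]) the stage handed to this function
#' is chosen by `config$segment_stage`.
#'
#' @param img [rgb_image()] to segment.
#' @param biomarker biomarker name or alias.
#' @param config configuration list.
#' @return a `segmentation_result`.
#' @export
segment <- function(img, biomarker, config = ihc_config()) {
  thr <- select_thresholds(biomarker, config)
  candidate <- threshold_band(img, thr)
  watershed_segment(img, candidate, config$morphology,
                    params_used = list(biomarker = attr(thr, "biomarker"),
                                       lower = unname(thr[["lower"]]),
                                       upper = unname(thr[["upper"]])))
}
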