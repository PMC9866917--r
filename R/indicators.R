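# The two diagnostic indicators per biomarker image: relative positive
# area (deltaS = Sp/Sw) and the ordinal staining-intensity coefficient KI
# derived from the mean luma of the segmented regions.

#' Relative positive area
#'
#' deltaS = Sp / Sw: the fraction of the field-of-view window covered by
#' positive-cell pixels. Exact rational arithmetic on pixel counts.
#'
#' @param result a `segmentation_result`.
#' @return list with `delta_s`, `sp`, `sw`.
#' @export
relative_area <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  sp <- result$positive_area_sp; sw <- result$window_area_sw
  if (sw <= 0) stop("relative_area: window area Sw must be positive")
  list(delta_s = sp / sw, sp = sp, sw = sw)
}

#' Mean brightness of masked pixels
#'
#' Mean luma of the image restricted to the mask — the segmented regions
#' superimposed on the (by default unenhanced) input image.
#'
#' @param original [rgb_image()] to measure on.
#' @param mask logical matrix matching the image.
#' @return scalar mean luma in \[0, 255\].
#' @export
masked_mean_brightness <- function(original, mask) {
  assert_rgb(original, "original")
  if (!is.matrix(mask) || !identical(dim(mask), dim(original)[1:2]))
    stop("mask dimensions must match the image")
  mode(mask) <- "logical"
  if (!any(mask))
    stop("no positive cells: the mask is empty, masked brightness is undefined")
  mean(luma(original)[mask])
}

#' Staining-intensity coefficient
#'
#' Ordinal 1-3 score from mean brightness Y of the segmented regions:
#' KI = 1 for Y <= 15, KI = 2 for 15 < Y <= 30, KI = 3 for Y > 30
#' (half-open bins close the printed integer gap at (15, 16)).
#'
#' @param mean_brightness scalar in \[0, 255\].
#' @param bins optional replacement bin table (columns y_min, y_max, ki).
#' @return list with `ki` (integer) and `mean_brightness`.
#' @export
intensity_coefficient <- function(mean_brightness, bins = NULL) {
  y <- mean_brightness
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y < 0 || y > 255)
    stop("intensity_coefficient: mean_brightness must lie in [0, 255]")
  if (is.null(bins)) bins <- ihc_default_config()$ki_bins
  hit <- which(y > bins$y_min & y <= bins$y_max)
  if (length(hit) != 1L) stop("intensity bins do not partition [0, 255]")
  list(ki = as.integer(bins$ki[hit]), mean_brightness = y)
}

#' Construct an indicator set directly
#'
#' Mainly for testing the rule systems without images: per-biomarker
#' relative areas and intensity levels.
#'
#' @param sigma_s named numeric vector of relative areas (names in
#'   PR/ER/HER2/KI67), values in \[0, 1\].
#' @param ki named integer vector of intensity levels in \{1, 2, 3\}
#'   (NA = no positive cells); missing biomarkers default to NA.
#' @param mean_brightness optional named numeric vector.
#' @param provenance optional named list of provenance records.
#' @return object of class `indicator_set`: named list of per-biomarker
#'   entries `sigma_s`, `ki`, `mean_brightness`, `no_positive_cells`.
#' @export
indicator_set <- function(sigma_s, ki = NULL, mean_brightness = NULL,
                          provenance = NULL) {
  missing <- setdiff(BIOMARKERS, names(sigma_s))
  if (length(missing))
    stop("incomplete indicator set, missing biomarker(s): ",
         paste(missing, collapse = ", "))
  if (any(sigma_s < 0 | sigma_s > 1)) stop("sigma_s values must lie in [0, 1]")
  out <- lapply(BIOMARKERS, function(bm) {
    k <- if (!is.null(ki) && bm %in% names(ki)) as.integer(ki[[bm]]) else NA_integer_
    if (!is.na(k) && !k %in% 1:3) stop("ki values must be 1, 2 or 3 (or NA)")
    mb <- if (!is.null(mean_brightness) && bm %in% names(mean_brightness))
      mean_brightness[[bm]] else NA_real_
    list(sigma_s = unname(sigma_s[[bm]]), ki = k, mean_brightness = mb,
         no_positive_cells = is.na(k) && sigma_s[[bm]] == 0,
         provenance = provenance[[bm]])
  })
  names(out) <- BIOMARKERS
  structure(out, class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("<indicator_set>\n")
  for (bm in BIOMARKERS)
    cat(sprintf("  %-4s sigmaS = %.4f  KI = %s%s\n", bm, x[[bm]]$sigma_s,
                ifelse(is.na(x[[bm]]$ki), "NA", x[[bm]]$ki),
                if (isTRUE(x[[bm]]$no_positive_cells)) "  [no positive cells]" else ""))
  invisible(x)
}

#' Compute the full indicator set for a case
#'
#' For each of the four biomarker images: preprocess, segment (the stage
#' selected by `config$segment_stage`), then measure deltaS and — on the
#' image selected by `config$intensity_source` — the masked mean brightness
#' and KI. An empty mask yields KI = NA with a `no_positive_cells` flag.
#'
#' @param stack named list of [rgb_image()]s; names must cover
#'   PR, ER, HER2, KI67 (aliases accepted).
#' @param config configuration list.
#' @return an `indicator_set` whose entries also carry `sp`, `sw` and the
#'   per-image `provenance`.
#' @export
compute_indicator_set <- function(stack, config = ihc_config()) {
  if (is.null(names(stack))) stop("stack must be a named list of images")
  names(stack) <- vapply(names(stack), biomarker, character(1))
  missing <- setdiff(BIOMARKERS, names(stack))
  if (length(missing))
    stop("incomplete image stack, missing biomarker(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(BIOMARKERS, function(bm) {
    img <- stack[[bm]]
    assert_rgb(img, bm)
    pre <- preprocess(img, config)
    seg_img <- switch(config$segment_stage,
                      amplified = pre$image,
                      filtered = pre$stages$III,
                      stop("segment_stage must be 'amplified' or 'filtered'"))
    seg <- segment(seg_img, bm, config)
    area <- relative_area(seg)
    intens_img <- switch(config$intensity_source,
                         original = img,
                         amplified = pre$image,
                         stop("intensity_source must be 'original' or 'amplified'"))
    if (seg$positive_area_sp > 0L) {
      mb <- masked_mean_brightness(intens_img, seg$foreground_mask)
      ic <- intensity_coefficient(mb, config$ki_bins)
      ki <- ic$ki; nopos <- FALSE
    } else {
      mb <- NA_real_; ki <- NA_integer_; nopos <- TRUE
    }
    list(sigma_s = area$delta_s, sp = area$sp, sw = area$sw,
         ki = ki, mean_brightness = mb, no_positive_cells = nopos,
         provenance = pre$provenance, segmentation = seg)
  })
  names(out) <- BIOMARKERS
  structure(out, class = "indicator_set")
}
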