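# Seeded generator of IHC-like microscopy frames with exact ground truth:
# a light background, brown-stained positive nuclei and cool-blue negative
# nuclei drawn as ellipses, plus optional salt-and-pepper noise. Colors are
# parameterized by target luma: a hue offset with zero luma weight is added
# to a gray level, so the rendered luma equals the requested level up to
# integer rounding.

# channel offsets with (0.299, 0.587, 0.114) . offset = 0
.stain_offsets <- list(
  brown = c(30, -(0.299 * 30 - 0.114 * 60) / 0.587, -60),   # warm / DAB-like
  blue  = c(-40, -(-0.299 * 40 + 0.114 * 60) / 0.587, 60),  # cool / hematoxylin-like
  gray  = c(0, 0, 0)
)

# Scale the hue offset down when a channel would clip, so the rendered
# luma equals the requested level (up to rounding) even for very dark or
# very bright stains.
.stain_color <- function(target_luma, hue) {
  off <- .stain_offsets[[hue]]
  s <- 1
  for (k in 1:3) {
    if (off[k] > 0) s <- min(s, (255 - target_luma) / off[k])
    if (off[k] < 0) s <- min(s, target_luma / -off[k])
  }
  round(target_luma + max(s, 0) * off)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic IHC fixture
#'
#' @param height,width frame size in pixels (desk-scale default 512).
#' @param positive_fraction target fraction of the frame covered by
#'   positive nuclei, in \[0, 0.9\].
#' @param positive_luma mean luma of positive-nucleus pixels, in \[0, 255\].
#' @param negative_count number of counter-stained (negative) nuclei.
#' @param negative_luma mean luma of negative-nucleus pixels; choose a
#'   value outside the biomarker's threshold band.
#' @param nucleus_radius_px mean nucleus semi-axis in pixels.
#' @param nucleus_radius_spread half-range of per-nucleus radius jitter.
#' @param luma_jitter half-range of per-nucleus luma jitter.
#' @param pixel_jitter half-range of per-pixel luma jitter.
#' @param impulse_noise_density fraction of pixels hit by salt-and-pepper
#'   noise, in \[0, 0.5\].
#' @param background_luma background gray level.
#' @param allow_overlap may positive nuclei overlap? Default (`NULL`)
#'   permits overlap only when `positive_fraction` > 0.45, above which
#'   non-overlapping random placement cannot converge.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(height = 512L, width = 512L,
                         positive_fraction = 0.25, positive_luma = 195,
                         negative_count = 8L, negative_luma = 120,
                         nucleus_radius_px = 10, nucleus_radius_spread = 2,
                         luma_jitter = 3, pixel_jitter = 2,
                         impulse_noise_density = 0, background_luma = 245,
                         allow_overlap = NULL, seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 0.9)
    stop("positive_fraction must lie in [0, 0.9]")
  if (positive_luma < 0 || positive_luma > 255)
    stop("positive_luma must lie in [0, 255]")
  if (impulse_noise_density < 0 || impulse_noise_density > 0.5)
    stop("impulse_noise_density must lie in [0, 0.5]")
  if (nucleus_radius_px <= nucleus_radius_spread)
    stop("nucleus_radius_px must exceed nucleus_radius_spread")
  if (is.null(allow_overlap)) allow_overlap <- positive_fraction > 0.45
  structure(as.list(environment()), class = "fixture_spec")
}

# rasterize an ellipse; returns logical matrix patch plus row/col ranges
.ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  r_ext <- max(a, b)
  r0 <- max(1L, floor(cy - r_ext)); r1 <- min(h, ceiling(cy + r_ext))
  c0 <- max(1L, floor(cx - r_ext)); c1 <- min(w, ceiling(cx + r_ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  list(rows = rows, cols = cols, inside = u^2 + v^2 <= 1)
}

#' Generate a synthetic IHC image with ground truth
#'
#' Places elliptical positive nuclei (non-overlapping unless
#' `allow_overlap`) until the target positive-area fraction is met within
#' +/- 0.01, then negative nuclei in a cool hue, then renders colors and
#' finally applies impulse noise. Ground truth (exact positive mask, the
#' nucleus table, the exact pre-noise delta_S and masked mean luma) is
#' recorded before noise.
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (an [rgb_image()]) and `truth` (list:
#'   `positive_mask`, `nucleus_table`, `true_delta_s`, `true_mean_luma`,
#'   `clean_image`).
#' @export
make_ihc_image <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    h <- as.integer(spec$height); w <- as.integer(spec$width)
    r_max <- spec$nucleus_radius_px + spec$nucleus_radius_spread
    if (2 * r_max + 2 > min(h, w))
      stop(sprintf(
        "make_ihc_image: nucleus radius %.1f is infeasible for a %dx%d frame",
        r_max, h, w))
    npx <- as.numeric(h) * w
    pos_mask <- matrix(FALSE, h, w)
    occupied <- matrix(FALSE, h, w)   # includes a separation margin
    nuclei <- list()
    margin <- 2
    target <- spec$positive_fraction
    attempts <- 0L
    max_attempts <- 4000L + 40L * ceiling(target * npx /
                                          (pi * spec$nucleus_radius_px^2))
    while (sum(pos_mask) / npx < target - 0.01 ||
           (target > 0 && sum(pos_mask) == 0)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "make_ihc_image: cannot reach positive_fraction %.3f (reached %.3f after %d attempts)",
          target, sum(pos_mask) / npx, attempts))
      a <- spec$nucleus_radius_px + stats::runif(1, -1, 1) * spec$nucleus_radius_spread
      b <- a * stats::runif(1, 0.7, 1)
      # shrink the last nucleus rather than overshooting the target
      gap_px <- (target + 0.005) * npx - sum(pos_mask)
      if (pi * a * b > gap_px) {
        scale <- sqrt(max(gap_px, 0) / (pi * a * b))
        if (scale < 0.3) break     # close enough; a smaller blob would be debris
        a <- a * scale; b <- b * scale
      }
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 1 + a, h - a); cx <- stats::runif(1, 1 + a, w - a)
      ep <- .ellipse_pixels(h, w, cy, cx, a, b, theta)
      if (is.null(ep)) next
      if (!spec$allow_overlap) {
        guard <- .ellipse_pixels(h, w, cy, cx, a + margin, b + margin, theta)
        if (any(occupied[guard$rows, guard$cols][guard$inside])) next
        occ <- occupied[guard$rows, guard$cols]
        occ[guard$inside] <- TRUE
        occupied[guard$rows, guard$cols] <- occ
      }
      pm <- pos_mask[ep$rows, ep$cols]
      pm[ep$inside] <- TRUE
      pos_mask[ep$rows, ep$cols] <- pm
      nuclei[[length(nuclei) + 1L]] <-
        data.frame(center_row = cy, center_col = cx, semi_major = a,
                   semi_minor = b, theta = theta, class = "positive")
      if (target == 0) break
    }
    if (abs(sum(pos_mask) / npx - target) > 0.01)
      stop(sprintf("make_ihc_image: reached fraction %.4f, outside target %.2f +/- 0.01",
                   sum(pos_mask) / npx, target))

    # counter-stained nuclei go into the gaps; on crowded frames the
    # candidate radius shrinks progressively so placement still converges
    neg_mask <- matrix(FALSE, h, w)
    placed <- 0L; tries <- 0L; shrink <- 1
    while (placed < spec$negative_count && tries < 600L * max(spec$negative_count, 1L)) {
      tries <- tries + 1L
      if (tries %% 100L == 0L) shrink <- max(shrink * 0.85, 0.35)
      a <- shrink * (spec$nucleus_radius_px +
                     stats::runif(1, -1, 1) * spec$nucleus_radius_spread)
      b <- a * stats::runif(1, 0.7, 1)
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 1 + a, h - a); cx <- stats::runif(1, 1 + a, w - a)
      ep <- .ellipse_pixels(h, w, cy, cx, a + margin, b + margin, theta)
      if (is.null(ep)) next
      if (any(pos_mask[ep$rows, ep$cols][ep$inside]) ||
          any(neg_mask[ep$rows, ep$cols][ep$inside])) next
      ep <- .ellipse_pixels(h, w, cy, cx, a, b, theta)
      nm <- neg_mask[ep$rows, ep$cols]
      nm[ep$inside] <- TRUE
      neg_mask[ep$rows, ep$cols] <- nm
      placed <- placed + 1L
      nuclei[[length(nuclei) + 1L]] <-
        data.frame(center_row = cy, center_col = cx, semi_major = a,
                   semi_minor = b, theta = theta, class = "negative")
    }
    if (placed < spec$negative_count)
      stop("make_ihc_image: could not place the requested negative nuclei")

    # render: background, then nuclei with per-nucleus and per-pixel jitter
    bg <- .stain_color(spec$background_luma, "gray") + c(2, 0, -3)
    img <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- as.integer(bg[ch])
    nucleus_table <- do.call(rbind, nuclei)
    draw_class <- function(img, rows, hue, base_luma) {
      for (k in rows) {
        nuc <- nucleus_table[k, ]
        ep <- .ellipse_pixels(h, w, nuc$center_row, nuc$center_col,
                              nuc$semi_major, nuc$semi_minor, nuc$theta)
        lum_k <- base_luma + stats::runif(1, -1, 1) * spec$luma_jitter
        col_k <- .stain_color(lum_k, hue)
        n_in <- sum(ep$inside)
        pj <- if (spec$pixel_jitter > 0)
          sample(seq(-spec$pixel_jitter, spec$pixel_jitter), n_in, replace = TRUE)
        else integer(n_in)
        for (ch in 1:3) {
          sl <- img[ep$rows, ep$cols, ch]
          sl[ep$inside] <- pmin(pmax(col_k[ch] + pj, 0L), 255L)
          img[ep$rows, ep$cols, ch] <- sl
        }
      }
      img
    }
    if (!is.null(nucleus_table)) {
      img <- draw_class(img, which(nucleus_table$class == "positive"),
                        "brown", spec$positive_luma)
      img <- draw_class(img, which(nucleus_table$class == "negative"),
                        "blue", spec$negative_luma)
    } else {
      nucleus_table <- data.frame(center_row = numeric(0), center_col = numeric(0),
                                  semi_major = numeric(0), semi_minor = numeric(0),
                                  theta = numeric(0), class = character(0))
    }
    clean <- rgb_image(img)
    truth <- list(
      positive_mask = pos_mask,
      nucleus_table = nucleus_table,
      true_delta_s = sum(pos_mask) / npx,
      true_mean_luma = if (any(pos_mask)) mean(luma(clean)[pos_mask]) else NA_real_,
      clean_image = clean)
    out_img <- if (spec$impulse_noise_density > 0)
      add_impulse_noise(clean, spec$impulse_noise_density,
                        seed = spec$seed + 1L)
    else clean
    list(image = out_img, truth = truth)
  })
}

#' Add salt-and-pepper impulse noise
#'
#' A seeded random subset of pixels (exactly `round(density * n)`, sampled
#' without replacement) is set to 0 or 255 with equal probability; all
#' three channels of a hit pixel are corrupted jointly.
#'
#' @param img an [rgb_image()].
#' @param density fraction of pixels to corrupt, in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @return noisy [rgb_image()].
#' @export
add_impulse_noise <- function(img, density, seed = 1L) {
  assert_rgb(img)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 0.5)
    stop("add_impulse_noise: density must lie in [0, 0.5]")
  if (density == 0) return(img)
  .with_seed(seed, {
    n <- prod(dim(img)[1:2])
    k <- round(density * n)
    idx <- sample.int(n, k)
    val <- sample(c(0L, 255L), k, replace = TRUE)
    out <- unclass(img)
    npx <- dim(img)[1] * dim(img)[2]
    for (ch in 1:3) out[idx + (ch - 1L) * npx] <- val
    rgb_image(out)
  })
}
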