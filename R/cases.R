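# Fixture quadruples parameterized to each published rule system. One
# shared parameterization used by the tests, the CLI example and the
# acceptance script.
#
# Two regimes are needed because the published chain thresholds the
# alpha-amplified image while intensity is scored on the raw input:
# * "dark" cases (Luminal B, HER2-amplified, basal-like) use dim nuclei on
#   a bright field; the gain lifts nucleus luma into the published band
#   while the raw masked mean stays low enough to exercise every KI level,
#   exactly the regime the published parameters imply.
# * Luminal A demands ER coverage > 0.66 with ER KI = 3, which is
#   arithmetically unreachable through the amplifying chain (the Y-gain
#   feedback: high dark coverage forces a gain too large for the band, and
#   band/gain quotients cap the raw mean at 30). That quadruple is
#   generated with in-band raw stains and classified with
#   segment_stage = "filtered".

.case_params <- list(
  LuminalA = list(
    config = list(segment_stage = "filtered"),
    grade = "G1",
    images = list(
      ER   = list(fraction = 0.75, luma = 195, jitter = 3, pjitter = 2),
      PR   = list(fraction = 0.30, luma = 170, jitter = 3, pjitter = 2),
      HER2 = list(fraction = 0,    luma = 120, jitter = 3, pjitter = 2),
      KI67 = list(fraction = 0.08, luma = 170, jitter = 3, pjitter = 2))),
  LuminalB = list(
    config = list(),
    grade = "G3",
    images = list(
      # gain 6 maps [186, 198] into the ER band; raw mean 32 keeps KI = 3
      ER   = list(fraction = 0.30, luma = 32, jitter = 1, pjitter = 0),
      PR   = list(fraction = 0,    luma = 32, jitter = 1, pjitter = 0),
      # gain 4 maps ~[42, 54] into the wide HER2 band; raw mean 12 -> KI = 1
      HER2 = list(fraction = 0.05, luma = 12, jitter = 1, pjitter = 0, radius = 14),
      # gain 6 maps [162, 174] into the KI67 band
      KI67 = list(fraction = 0.30, luma = 28, jitter = 1, pjitter = 0))),
  HER2Amplified = list(
    config = list(),
    grade = "G3",
    images = list(
      ER   = list(fraction = 0,    luma = 32, jitter = 1, pjitter = 0),
      PR   = list(fraction = 0,    luma = 32, jitter = 1, pjitter = 0),
      HER2 = list(fraction = 0.05, luma = 12, jitter = 1, pjitter = 0, radius = 14),
      # low coverage keeps Y > 200 -> gain 4 -> 112, outside the KI67 band
      KI67 = list(fraction = 0.15, luma = 28, jitter = 1, pjitter = 0))),
  BasalLike = list(
    config = list(),
    grade = "G3",
    images = list(
      ER   = list(fraction = 0,    luma = 42, jitter = 1, pjitter = 0),
      PR   = list(fraction = 0,    luma = 42, jitter = 1, pjitter = 0),
      HER2 = list(fraction = 0,    luma = 42, jitter = 1, pjitter = 0),
      # gain 4 maps [164, 174] into the KI67 band; raw mean 42 -> KI = 3
      KI67 = list(fraction = 0.15, luma = 42, jitter = 1, pjitter = 0)))
)

#' Generate a four-image case parameterized to a published subtype
#'
#' Produces a stack of four synthetic biomarker images whose indicator
#' values satisfy exactly one published rule system, together with the
#' configuration under which the pipeline should classify it and the
#' associated grade.
#'
#' @param subtype `"LuminalA"`, `"LuminalB"`, `"HER2Amplified"` or
#'   `"BasalLike"`.
#' @param seed integer seed.
#' @param height,width frame size (desk-scale default 256).
#' @param impulse_noise_density salt-and-pepper density applied to every
#'   image of the stack.
#' @return list with `stack` (named list of images), `truth` (per-image
#'   ground truth), `config` (list of config overrides to classify with),
#'   `grade` and `expected_subtype`.
#' @export
make_subtype_case <- function(subtype, seed = 1L, height = 256L, width = 256L,
                              impulse_noise_density = 0.01) {
  if (!subtype %in% names(.case_params))
    stop("subtype must be one of ", paste(names(.case_params), collapse = ", "))
  p <- .case_params[[subtype]]
  stack <- list(); truth <- list()
  for (i in seq_along(BIOMARKERS)) {
    bm <- BIOMARKERS[i]
    im <- p$images[[bm]]
    spec <- fixture_spec(
      height = height, width = width,
      positive_fraction = im$fraction, positive_luma = im$luma,
      # a dense positive carpet leaves no room for counter-stained nuclei
      negative_count = if (im$fraction > 0.5) 0L else 6L, negative_luma = 120,
      nucleus_radius_px = if (is.null(im$radius)) 10 else im$radius,
      nucleus_radius_spread = 2,
      luma_jitter = im$jitter, pixel_jitter = im$pjitter,
      impulse_noise_density = impulse_noise_density,
      seed = seed * 101L + i)
    fx <- make_ihc_image(spec)
    stack[[bm]] <- fx$image
    truth[[bm]] <- fx$truth
  }
  list(stack = stack, truth = truth, config = p$config, grade = p$grade,
       expected_subtype = subtype)
}
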