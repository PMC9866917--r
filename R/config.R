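#' Default pipeline configuration
#'
#' All tunable parameters in one place, preset to the published values.
#' A configuration is a plain named list; [ihc_config()] merges user
#' overrides (a list or a JSON file path) over these defaults.
#'
#' Fields:
#' \describe{
#'   \item{probe_window}{median window used for the PSNR probe (3).}
#'   \item{alpha_table}{brightness-gain bins: gain 20/12/8/6/4 for
#'     Y <= 10 / (10,40] / (40,150] / (150,200] / > 200.}
#'   \item{thresholds}{per-biomarker luma bands: PR (160,180), ER (180,210),
#'     HER2 (40,230), KI67 (160,180).}
#'   \item{morphology}{marker-watershed recipe: `open_iter` 2, `dilate_iter`
#'     3, `dist_frac` 0.4, `min_object_px` 30.}
#'   \item{segment_stage}{which stage the threshold band is applied to:
#'     `"amplified"` (the literal published chain, alpha x filtered) or
#'     `"filtered"` (the unamplified filtered image).}
#'   \item{intensity_source}{image on which masked mean brightness (hence
#'     KI) is measured: `"original"` (default; keeps KI independent of the
#'     gain) or `"amplified"`.}
#'   \item{bcb_ki_binding}{biomarker whose KI the unqualified "KI = 1"
#'     condition of the Luminal B and HER2-amplified systems refers to
#'     (default `"HER2"`, the most local reading of the printed systems).}
#'   \item{her2_amplified_area_direction}{`"lt"` evaluates the printed
#'     HER2 sigma_S < 0.1 condition of the HER2-amplified system as printed;
#'     `"gt"` flips it (the printed direction is biologically suspect).}
#' }
#'
#' @return named list of defaults.
#' @export
ihc_default_config <- function() {
  list(
    probe_window = 3L,
    alpha_table = data.frame(
      y_min = c(-Inf, 10, 40, 150, 200),
      y_max = c(10, 40, 150, 200, Inf),
      alpha = c(20L, 12L, 8L, 6L, 4L)
    ),
    window_rule = data.frame(
      psnr_min = c(-Inf, 20),
      psnr_max = c(20, Inf),
      side = c(5L, 3L)
    ),
    thresholds = list(
      PR   = c(lower = 160, upper = 180),
      ER   = c(lower = 180, upper = 210),
      HER2 = c(lower = 40,  upper = 230),
      KI67 = c(lower = 160, upper = 180)
    ),
    ki_bins = data.frame(
      y_min = c(-Inf, 15, 30),
      y_max = c(15, 30, Inf),
      ki = c(1L, 2L, 3L)
    ),
    morphology = list(open_iter = 2L, dilate_iter = 3L,
                      dist_frac = 0.4, min_object_px = 30L),
    segment_stage = "amplified",
    intensity_source = "original",
    bcb_ki_binding = "HER2",
    her2_amplified_area_direction = "lt"
  )
}

#' Build an effective configuration
#'
#' @param overrides NULL, a named list of overrides, or a path to a JSON
#'   file of overrides. Nested lists merge field-by-field; data-frame-valued
#'   families (alpha table, window rule, KI bins) are replaced wholesale.
#' @return effective configuration list.
#' @export
ihc_config <- function(overrides = NULL) {
  cfg <- ihc_default_config()
  if (is.null(overrides)) return(cfg)
  if (is.character(overrides) && length(overrides) == 1L) {
    if (!file.exists(overrides)) stop("config file not found: ", overrides)
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  }
  if (!is.list(overrides)) stop("config overrides must be a list or a JSON path")
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) {
    if (nm == "thresholds" || nm == "morphology") {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(overrides[[nm]]))
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

#' Digest of the effective configuration
#'
#' Changes iff any effective parameter changes; recorded in case reports so
#' results can be traced to the exact parameterization.
#' @param config configuration list.
#' @return character digest.
#' @export
config_digest <- function(config) digest::digest(config)
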