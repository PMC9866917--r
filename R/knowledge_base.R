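# IF-THEN rule store binding image measurements (probe PSNR, mean
# brightness) and the biomarker kind to algorithm parameters. Three
# families: "window" (median filter side), "threshold" (per-biomarker
# band), "alpha" (brightness gain). Rules within a family must partition
# their input space so that exactly one rule fires for any input.

.kb_default <- function() {
  list(
    window = list(
      list(id = "window_psnr_le_20", psnr_min = -Inf, psnr_max = 20, side = 5L),
      list(id = "window_psnr_gt_20", psnr_min = 20, psnr_max = Inf, side = 3L)
    ),
    threshold = list(
      list(id = "threshold_pr",   image_type = "PR",   lower = 160, upper = 180),
      list(id = "threshold_er",   image_type = "ER",   lower = 180, upper = 210),
      list(id = "threshold_her2", image_type = "HER2", lower = 40,  upper = 230),
      list(id = "threshold_ki67", image_type = "KI67", lower = 160, upper = 180)
    ),
    alpha = list(
      list(id = "alpha_y_le_10",     y_min = -Inf, y_max = 10,  alpha = 20L),
      list(id = "alpha_y_10_to_40",  y_min = 10,   y_max = 40,  alpha = 12L),
      list(id = "alpha_y_40_to_150", y_min = 40,   y_max = 150, alpha = 8L),
      list(id = "alpha_y_150_to_200", y_min = 150, y_max = 200, alpha = 6L),
      list(id = "alpha_y_gt_200",    y_min = 200,  y_max = Inf, alpha = 4L)
    )
  )
}

.kb_validate <- function(rules) {
  for (fam in c("window", "alpha")) {
    rs <- rules[[fam]]
    if (length(rs) == 0L)
      stop("knowledge base: family '", fam, "' does not cover the input axis")
    lo <- vapply(rs, function(r) r[[if (fam == "window") "psnr_min" else "y_min"]], numeric(1))
    hi <- vapply(rs, function(r) r[[if (fam == "window") "psnr_max" else "y_max"]], numeric(1))
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    if (any(hi <= lo))
      stop("knowledge base: empty interval in family '", fam, "'")
    if (lo[1] != -Inf || hi[length(hi)] != Inf)
      stop("knowledge base: family '", fam, "' does not cover the input axis")
    if (length(lo) > 1 && any(abs(lo[-1] - hi[-length(hi)]) > 0)) {
      gap <- lo[-1] > hi[-length(hi)]
      stop("knowledge base: family '", fam, "' rules ",
           if (any(gap)) "leave a gap" else "overlap",
           " (conditions must partition the input space)")
    }
  }
  bms <- vapply(rules$threshold, function(r) r$image_type, character(1))
  if (!setequal(bms, BIOMARKERS) || anyDuplicated(bms))
    stop("knowledge base: threshold family must have exactly one rule per biomarker")
  for (r in rules$threshold)
    if (r$lower < 0 || r$upper > 255 || r$lower > r$upper)
      stop("knowledge base: invalid thresholds in rule '", r$id, "'")
  rules
}

#' Load the IF-THEN parameter-selection rules
#'
#' Defaults are the published rules: 2 window rules (5x5 iff probe PSNR <=
#' 20 dB), 4 threshold rules (one per biomarker) and 5 brightness-gain
#' bins. A JSON override file merges by parameter family: the "threshold"
#' family merges rule-by-rule (keyed by `image_type`), while the interval
#' families ("window", "alpha") are replaced wholesale when supplied, and
#' are then re-validated as a partition of their input axis.
#'
#' @param config optional path to a JSON ruleset, or an equivalent list.
#' @return object of class `rule_store`.
#' @export
load_rules <- function(config = NULL) {
  rules <- .kb_default()
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      if (!file.exists(config)) stop("ruleset file not found: ", config)
      parsed <- tryCatch(
        jsonlite::read_json(config, simplifyVector = FALSE),
        error = function(e) stop("malformed ruleset '", config, "': ",
                                 conditionMessage(e)))
      config <- parsed
    }
    if (!is.list(config)) stop("ruleset must be a list or a JSON path")
    unknown <- setdiff(names(config), names(rules))
    if (length(unknown))
      stop("unknown rule family(ies): ", paste(unknown, collapse = ", "))
    num <- function(x) if (is.character(x)) as.numeric(x) else x
    if (!is.null(config$threshold)) {
      for (ov in config$threshold) {
        bm <- biomarker(ov$image_type)
        k <- which(vapply(rules$threshold, function(r) r$image_type, character(1)) == bm)
        for (f in intersect(names(ov), c("lower", "upper")))
          rules$threshold[[k]][[f]] <- num(ov[[f]])
      }
    }
    for (fam in intersect(names(config), c("window", "alpha"))) {
      rules[[fam]] <- lapply(seq_along(config[[fam]]), function(i) {
        r <- config[[fam]][[i]]
        r[intersect(names(r), c("psnr_min", "psnr_max", "y_min", "y_max"))] <-
          lapply(r[intersect(names(r), c("psnr_min", "psnr_max", "y_min", "y_max"))], num)
        if (is.null(r$id)) r$id <- sprintf("%s_override_%d", fam, i)
        r
      })
    }
  }
  structure(.kb_validate(rules), class = "rule_store")
}

#' Fire a rule family on named inputs
#'
#' Pure lookup: evaluates the family's conditions on the inputs and
#' returns the unique matching rule's parameter assignment. The fired rule
#' id is attached as an attribute and logged (see [ihc_verbose()]).
#'
#' @param store a `rule_store` from [load_rules()].
#' @param family `"window"`, `"threshold"` or `"alpha"`.
#' @param inputs named list; `psnr_db` for window, `image_type` for
#'   threshold, `y` for alpha.
#' @return named list of assigned parameters with attribute `rule_id`.
#' @export
fire <- function(store, family, inputs) {
  stopifnot(inherits(store, "rule_store"))
  if (!family %in% names(store)) stop("unknown rule family '", family, "'")
  rs <- store[[family]]
  hit <- switch(family,
    window = {
      if (is.null(inputs$psnr_db)) stop("fire(window): input 'psnr_db' required")
      which(vapply(rs, function(r)
        inputs$psnr_db > r$psnr_min & inputs$psnr_db <= r$psnr_max, logical(1)))
    },
    threshold = {
      if (is.null(inputs$image_type)) stop("fire(threshold): input 'image_type' required")
      bm <- biomarker(inputs$image_type)
      which(vapply(rs, function(r) r$image_type == bm, logical(1)))
    },
    alpha = {
      if (is.null(inputs$y)) stop("fire(alpha): input 'y' required")
      which(vapply(rs, function(r)
        inputs$y > r$y_min & inputs$y <= r$y_max, logical(1)))
    })
  if (length(hit) == 0L)
    stop("uncovered input for family '", family, "': no rule matches")
  if (length(hit) > 1L)
    stop("ambiguous input for family '", family, "': several rules match")
  r <- rs[[hit]]
  action <- r[setdiff(names(r), c("id", "psnr_min", "psnr_max",
                                  "y_min", "y_max", "image_type"))]
  ihc_log("rule fired: %s -> %s", r$id,
          paste(sprintf("%s=%s", names(action), unlist(action)), collapse = " "))
  attr(action, "rule_id") <- r$id
  action
}

#' Toggle INFO logging of fired rules
#'
#' @param on logical; when TRUE, [fire()] and the CLI report each fired
#'   rule via `message()`.
#' @export
ihc_verbose <- function(on = TRUE) {
  options(ihcsubtype.verbose = isTRUE(on))
  invisible(on)
}

ihc_log <- function(fmt, ...) {
  if (isTRUE(getOption("ihcsubtype.verbose", FALSE)))
    message("[ihcsubtype] ", sprintf(fmt, ...))
  invisible(NULL)
}
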