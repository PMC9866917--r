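# The four molecular-genetic-subtype rule systems, evaluated on an
# indicator set. Inequalities are strict exactly as published; equality at
# a boundary satisfies neither side, so Indeterminate is a legitimate
# outcome. A condition on an NA intensity level (no positive cells)
# evaluates FALSE.

#' @export
SUBTYPES <- c("LuminalA", "LuminalB", "HER2Amplified", "BasalLike",
              "Indeterminate")

.cond <- function(x) !is.na(x) & x

#' Luminal A rule system
#'
#' Five conditions: ER sigma_S > 0.66, ER KI = 3, PR sigma_S > 0.2,
#' HER2 sigma_S < 0.1, KI67 sigma_S < 0.2.
#'
#' @param ind an `indicator_set`.
#' @param config configuration list.
#' @return named logical vector of the five conditions.
#' @export
is_luminal_a <- function(ind, config = ihc_config()) {
  stopifnot(inherits(ind, "indicator_set"))
  c(er_sigma_gt_0.66  = .cond(ind$ER$sigma_s > 0.66),
    er_ki_eq_3        = .cond(ind$ER$ki == 3L),
    pr_sigma_gt_0.2   = .cond(ind$PR$sigma_s > 0.2),
    her2_sigma_lt_0.1 = .cond(ind$HER2$sigma_s < 0.1),
    ki67_sigma_lt_0.2 = .cond(ind$KI67$sigma_s < 0.2))
}

#' Luminal B rule system
#'
#' Six conditions: ER sigma_S < 0.66, ER KI = 3, PR sigma_S < 0.2,
#' HER2 sigma_S < 0.1, KI = 1 (bound to `config$bcb_ki_binding`, HER2 by
#' default), KI67 sigma_S > 0.2.
#'
#' @inheritParams is_luminal_a
#' @return named logical vector of the six conditions.
#' @export
is_luminal_b <- function(ind, config = ihc_config()) {
  stopifnot(inherits(ind, "indicator_set"))
  kb <- biomarker(config$bcb_ki_binding)
  out <- c(er_sigma_lt_0.66  = .cond(ind$ER$sigma_s < 0.66),
           er_ki_eq_3        = .cond(ind$ER$ki == 3L),
           pr_sigma_lt_0.2   = .cond(ind$PR$sigma_s < 0.2),
           her2_sigma_lt_0.1 = .cond(ind$HER2$sigma_s < 0.1),
           ki_eq_1           = .cond(ind[[kb]]$ki == 1L),
           ki67_sigma_gt_0.2 = .cond(ind$KI67$sigma_s > 0.2))
  names(out)[5] <- sprintf("%s_ki_eq_1", tolower(kb))
  out
}

#' HER2/neu-amplified rule system
#'
#' Four conditions: HER2 sigma_S < 0.1 (as published; direction
#' configurable), KI = 1 (bound like Luminal B's), ER sigma_S < 0.1,
#' PR sigma_S < 0.1.
#'
#' @inheritParams is_luminal_a
#' @return named logical vector of the four conditions.
#' @export
is_her2_amplified <- function(ind, config = ihc_config()) {
  stopifnot(inherits(ind, "indicator_set"))
  kb <- biomarker(config$bcb_ki_binding)
  her2_area <- switch(config$her2_amplified_area_direction,
                      lt = .cond(ind$HER2$sigma_s < 0.1),
                      gt = .cond(ind$HER2$sigma_s > 0.1),
                      stop("her2_amplified_area_direction must be 'lt' or 'gt'"))
  out <- c(her2_sigma_lt_0.1 = her2_area,
           ki_eq_1           = .cond(ind[[kb]]$ki == 1L),
           er_sigma_lt_0.1   = .cond(ind$ER$sigma_s < 0.1),
           pr_sigma_lt_0.1   = .cond(ind$PR$sigma_s < 0.1))
  names(out)[2] <- sprintf("%s_ki_eq_1", tolower(kb))
  out
}

#' Basal-like rule system
#'
#' Four conditions: ER sigma_S < 0.1, PR sigma_S < 0.1, HER2 sigma_S < 0.1,
#' KI67 KI = 3.
#'
#' @inheritParams is_luminal_a
#' @return named logical vector of the four conditions.
#' @export
is_basal_like <- function(ind, config = ihc_config()) {
  stopifnot(inherits(ind, "indicator_set"))
  c(er_sigma_lt_0.1   = .cond(ind$ER$sigma_s < 0.1),
    pr_sigma_lt_0.1   = .cond(ind$PR$sigma_s < 0.1),
    her2_sigma_lt_0.1 = .cond(ind$HER2$sigma_s < 0.1),
    ki67_ki_eq_3      = .cond(ind$KI67$ki == 3L))
}

# published subtype <-> grade associations (warnings only)
.grade_assoc <- list(LuminalA = c("G1", "G2"),
                     LuminalB = c("G2", "G3"),
                     HER2Amplified = "G3")

#' Classify an indicator set into a molecular subtype
#'
#' Evaluates all four rule systems. Exactly one fully satisfied system
#' yields that subtype; zero or several yield `Indeterminate`, always with
#' full per-condition detail. A supplied grade never changes the decision;
#' it only triggers a warning message in the result when the published
#' subtype/grade association is contradicted (Luminal A: G1/G2; Luminal B:
#' G2/G3; HER2-amplified: G3).
#'
#' @param ind an `indicator_set` covering all four biomarkers.
#' @param grade optional histological grade, see [grade()].
#' @param config configuration list.
#' @return `subtype_result`: list with `subtype`, `satisfied`
#'   (per-system condition vectors), `matched_systems`, `grade`,
#'   `grade_warnings`.
#' @export
classify <- function(ind, grade = NULL, config = ihc_config()) {
  if (!inherits(ind, "indicator_set"))
    stop("classify: expected an indicator_set")
  missing <- setdiff(BIOMARKERS, names(ind))
  if (length(missing))
    stop("incomplete indicator set, missing biomarker(s): ",
         paste(missing, collapse = ", "))
  g <- .normalize_grade(grade)
  satisfied <- list(LuminalA = is_luminal_a(ind, config),
                    LuminalB = is_luminal_b(ind, config),
                    HER2Amplified = is_her2_amplified(ind, config),
                    BasalLike = is_basal_like(ind, config))
  matched <- names(satisfied)[vapply(satisfied, all, logical(1))]
  subtype <- if (length(matched) == 1L) matched else "Indeterminate"
  warnings <- character(0)
  if (!is.null(g) && subtype %in% names(.grade_assoc) &&
      !g %in% .grade_assoc[[subtype]]) {
    warnings <- sprintf(
      "subtype %s is associated with grade %s but grade %s was supplied",
      subtype, paste(.grade_assoc[[subtype]], collapse = "/"), g)
  }
  structure(list(subtype = subtype, satisfied = satisfied,
                 matched_systems = matched, grade = g,
                 grade_warnings = warnings),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("<subtype: %s>\n", x$subtype))
  for (sys in names(x$satisfied)) {
    v <- x$satisfied[[sys]]
    cat(sprintf("  %-13s %s  [%s]\n", sys,
                if (all(v)) "SATISFIED" else "not satisfied",
                paste(sprintf("%s=%s", names(v), ifelse(v, "T", "F")),
                      collapse = " ")))
  }
  for (w in x$grade_warnings) cat("  warning:", w, "\n")
  invisible(x)
}
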