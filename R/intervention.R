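# Treatment packages per cohort and combination of component relative
# risks into one effective per-outcome relative risk.

#' Combine component relative risks with overlap correction
#'
#' Multiplying independent relative risks overstates the joint effect when
#' interventions act on overlapping pathways. For two or more components
#' the combined relative risk is corrected as
#' `1 - (1 - prod(rrs)) * overlap_factor`; a single component (or none) is
#' returned unchanged, since the correction applies only where multiple
#' interventions are involved.
#'
#' @param rrs numeric vector of positive relative risks
#' @param overlap_factor attenuation of the combined risk reduction,
#'   in (0,1]; default 0.8
#' @return combined relative risk
#' @export
combine_relative_risks <- function(rrs, overlap_factor = 0.8) {
  if (any(rrs <= 0)) .stopf("relative risks must be positive")
  if (!(overlap_factor > 0 && overlap_factor <= 1)) {
    .stopf("overlap_factor must be in (0,1]")
  }
  if (length(rrs) == 0L) return(1.0)
  if (length(rrs) == 1L) return(rrs)
  1 - (1 - prod(rrs)) * overlap_factor
}

#' Scale a relative risk by treatment adherence
#'
#' Linear attenuation of the risk reduction: `1 - adherence * (1 - rr)`.
#' Full adherence returns `rr`; zero adherence removes the effect.
#'
#' @param rr relative risk (> 0)
#' @param adherence proportion adherent, in `[0, 1]`
#' @return adherence-adjusted relative risk
#' @export
apply_adherence <- function(rr, adherence) {
  if (rr <= 0) .stopf("rr must be positive")
  if (!.is_prob(adherence)) .stopf("adherence must be in [0,1]")
  1 - adherence * (1 - rr)
}

#' Build the treatment package for a cohort
#'
#' Component selection follows the program protocol: the low-risk cohort
#' without diabetes is screened only (empty package); moderate risk
#' receives one antihypertensive agent (ACE inhibitor) plus statin and
#' lifestyle counseling; high risk adds a thiazide diuretic; very high
#' risk adds a beta-blocker. Cohorts with diabetes additionally receive
#' metformin (all) and a sulfonylurea (high and very high). Lifestyle
#' counseling is part of every treated package.
#'
#' @param cohort_label one of `"low"`, `"moderate"`, `"high"`, `"very_high"`
#' @param diabetic logical scenario flag
#' @param treatments named list of [treatment_effect()] objects to draw
#'   components from; default = the packaged published values
#' @param overlap_factor passed through to [combine_relative_risks()]
#' @return an `irapen_package` object
#' @export
build_package <- function(cohort_label, diabetic,
                          treatments = NULL, overlap_factor = 0.8) {
  if (!cohort_label %in% COHORT_LABELS) .stopf("unknown cohort label '%s'", cohort_label)
  if (is.null(treatments)) treatments <- .treatments_from_table(base_case_tables())
  antihypertensives <- switch(cohort_label,
    low = character(),
    moderate = "ace_inhibitor",
    high = c("ace_inhibitor", "thiazide"),
    very_high = c("ace_inhibitor", "thiazide", "beta_blocker")
  )
  comp_names <- if (cohort_label == "low" && !diabetic) {
    character()  # screening only
  } else if (cohort_label == "low") {
    c("metformin", "lifestyle_counseling")
  } else {
    c(antihypertensives, "statin",
      if (diabetic) c("metformin", if (cohort_label %in% c("high", "very_high")) "sulfonylurea"),
      "lifestyle_counseling")
  }
  missing <- setdiff(comp_names, names(treatments))
  if (length(missing)) .stopf("treatment library lacks: %s", paste(missing, collapse = ", "))
  structure(list(
    cohort_label = cohort_label, diabetic = diabetic,
    components = treatments[comp_names], overlap_factor = overlap_factor
  ), class = "irapen_package")
}

#' Effective per-outcome relative risk of a treatment package
#'
#' Combines the package components' per-outcome relative risks with the
#' overlap correction, then scales by adherence. An empty package has no
#' effect (relative risk 1).
#'
#' @param package an [build_package()] object
#' @param outcome `"chd"` or `"stroke"`
#' @param adherence proportion adherent, in `[0, 1]`
#' @return effective relative risk
#' @export
effective_rr <- function(package, outcome = c("chd", "stroke"), adherence = 1) {
  outcome <- match.arg(outcome)
  if (length(package$components) == 0L) return(1.0)
  rrs <- vapply(package$components, function(t) t[[paste0("rr_", outcome)]], numeric(1))
  apply_adherence(combine_relative_risks(rrs, package$overlap_factor), adherence)
}
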