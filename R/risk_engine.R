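# Framingham-type 10-year CVD risk, WHO/ISH band classification, and
# conversion of 10-year risks to annual event probabilities.

#' Load a risk-equation coefficient set
#'
#' The packaged default is the Framingham general cardiovascular risk
#' profile (Cox proportional-hazards form on log-transformed continuous
#' risk factors, sex-specific), which predicts total 10-year CVD risk.
#' Total CVD risk is split into CHD and stroke components by the
#' configured `chd_stroke_split` ratio. Alternative published coefficient
#' sets can be supplied as a YAML file of the same shape; coefficients are
#' never hard-coded.
#'
#' @param path YAML coefficient file; default = the packaged set
#' @return an `irapen_risk_coeffs` object
#' @export
load_risk_coefficients <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("framingham_general_cvd.yaml")
  cf <- yaml::read_yaml(path)
  for (sex in c("male", "female")) {
    s <- cf[[sex]]
    if (is.null(s) || length(s$coefficients) == 0L) {
      .stopf("coefficient set missing non-empty '%s' block", sex)
    }
    if (!(s$baseline_survival > 0 && s$baseline_survival <= 1)) {
      .stopf("baseline_survival for %s must be in (0,1]", sex)
    }
  }
  structure(cf, class = "irapen_risk_coeffs")
}

#' 10-year CVD risk for an index-cohort profile
#'
#' Evaluates the Cox survival form
#' `risk = 1 - S0 ^ exp(lp - mean_lp)` where `lp` is the linear predictor
#' over log(age), log(total cholesterol), log(HDL), log(SBP), smoking and
#' diabetes. Ages outside the equation's validity range (30-74) are
#' clamped, with a warning unless `warn_clamp = FALSE` (the Markov engine
#' clamps silently for the oldest cycles and documents it).
#'
#' @param profile an [risk_profile()] object (or a list with the same
#'   fields plus optional `age` override)
#' @param coeffs an `irapen_risk_coeffs` set
#' @param age evaluate at this age instead of `profile$age_entry`
#' @param warn_clamp warn when the age is clamped into the validity range
#' @return 10-year risk, a probability in (0,1)
#' @export
ten_year_risk <- function(profile, coeffs, age = NULL, warn_clamp = TRUE) {
  if (is.null(age)) age <- profile$age_entry
  rng <- unlist(coeffs$age_range)
  if (age < rng[1] || age > rng[2]) {
    if (warn_clamp) {
      warning(sprintf("age %s outside equation validity range [%d, %d]; clamped",
                      age, rng[1], rng[2]), call. = FALSE)
    }
    age <- min(max(age, rng[1]), rng[2])
  }
  s <- coeffs[[profile$sex]]
  co <- s$coefficients
  needed <- c("ln_age", "ln_total_cholesterol", "ln_hdl", "ln_sbp_untreated",
              "smoker", "diabetic")
  missing <- setdiff(needed, names(co))
  if (length(missing)) .stopf("coefficient set lacks: %s", paste(missing, collapse = ", "))
  lp <- co$ln_age * log(age) +
    co$ln_total_cholesterol * log(profile$total_cholesterol) +
    co$ln_hdl * log(profile$hdl) +
    co$ln_sbp_untreated * log(profile$sbp) +
    co$smoker * as.numeric(profile$smoker) +
    co$diabetic * as.numeric(profile$diabetic)
  risk <- 1 - s$baseline_survival^exp(lp - s$mean_lp)
  min(max(risk, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Convert a 10-year event probability to an annual probability
#'
#' Constant-hazard assumption: `p1 = 1 - (1 - p10)^(1/10)`.
#'
#' @param ten_year_risk probability in `[0, 1)`
#' @return annual probability, always `<=` the input
#' @export
annual_probability <- function(ten_year_risk) {
  if (any(ten_year_risk < 0 | ten_year_risk >= 1)) {
    .stopf("ten_year_risk must be in [0, 1)")
  }
  1 - (1 - ten_year_risk)^(1 / 10)
}

#' Classify a 10-year CVD risk into its WHO/ISH band
#'
#' Half-open bands: low `[0, 0.10)`, moderate `[0.10, 0.20)`, high
#' `[0.20, 0.30)`, very_high `[0.30, 1]`. The two published bands above
#' 30% are merged because they receive the same intervention.
#'
#' @param ten_year_risk probability in `[0, 1]`
#' @return a cohort label
#' @export
classify_who_ish <- function(ten_year_risk) {
  if (any(ten_year_risk < 0 | ten_year_risk > 1)) .stopf("risk must be in [0,1]")
  cuts <- c(-Inf, 0.10, 0.20, 0.30, Inf)
  COHORT_LABELS[findInterval(ten_year_risk, cuts[-1]) + 1L]
}

#' Background mortality net of CHD and stroke deaths
#'
#' Subtracts the CHD+stroke-attributable death probability from the
#' all-cause probability at one age, so that cardiovascular deaths are
#' not double-counted against the model's own event fatality.
#'
#' @param age age in years; must be covered by the table
#' @param life_table data.frame with columns `age`, `qx` (all-cause)
#' @param cvd_death_rates data.frame with columns `age`, `qx_cvd`
#'   (CHD+stroke attributable), or a single number applied at all ages
#' @return net annual death probability, floored at 0
#' @export
net_background_mortality <- function(age, life_table, cvd_death_rates) {
  i <- match(age, life_table$age)
  if (is.na(i)) .stopf("age %s not covered by the life table", age)
  qx <- life_table$qx[i]
  cvd <- if (is.data.frame(cvd_death_rates)) {
    j <- match(age, cvd_death_rates$age)
    if (is.na(j)) .stopf("age %s not covered by the CVD death-rate table", age)
    cvd_death_rates$qx_cvd[j]
  } else {
    cvd_death_rates
  }
  if (cvd > qx) {
    .stopf("CVD-attributable death rate (%g) exceeds all-cause rate (%g) at age %s",
           cvd, qx, age)
  }
  max(qx - cvd, 0)
}

# Annual CHD/stroke event probabilities for the cohort at a given age.
# per_cycle mode re-evaluates the risk equation as the cohort ages (the
# treatment relative risks stay constant); fixed mode holds the entry-age
# incidence for the whole horizon.
baseline_event_probs <- function(params, age) {
  mode <- if (is.null(params$risk)) "fixed" else params$risk$mode
  if (mode == "fixed" || age == params$profile$age_entry) {
    return(c(chd = params$annual_incidence_chd,
             stroke = params$annual_incidence_stroke))
  }
  p10 <- ten_year_risk(params$profile, params$risk$coefficients,
                       age = age, warn_clamp = FALSE)
  p1 <- annual_probability(p10)
  split <- params$risk$chd_stroke_split
  c(chd = p1 * split, stroke = p1 * (1 - split))
}
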