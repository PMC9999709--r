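# Domain types are plain nested lists with S3 class tags and explicit
# validators, serialized losslessly to JSON (YAML and JSON both accepted on
# input). Every parameter carries a provenance tag in params$provenance:
# "printed" (taken from the published program tables), "derived" (arithmetic
# on printed values), or "synthetic" (supplied by the synthetic-data module
# because the original input was never published).

#' Construct an index-cohort risk profile
#'
#' An index cohort is a hypothetical homogeneous cohort defined by one
#' risk-factor profile representing a WHO/ISH 10-year CVD risk band.
#' The representative scalar values (`sbp`, `total_cholesterol`) are the
#' single points inside the published bands at which the Framingham-type
#' risk equations are evaluated.
#'
#' @param cohort_label one of `"low"`, `"moderate"`, `"high"`, `"very_high"`
#' @param age_entry entry age in years (the program screens from age 40)
#' @param sex `"male"` or `"female"`
#' @param sbp_band systolic blood pressure band, mmHg, `c(lo, hi)`
#' @param sbp representative SBP within the band, mmHg
#' @param total_cholesterol_band total cholesterol band, mg/dl, `c(lo, hi)`
#' @param total_cholesterol representative total cholesterol, mg/dl
#' @param hdl HDL cholesterol, mg/dl
#' @param smoker,diabetic logical risk-factor flags
#' @return an object of class `irapen_profile`
#' @export
risk_profile <- function(cohort_label, age_entry = 40, sex,
                         sbp_band, sbp,
                         total_cholesterol_band, total_cholesterol,
                         hdl, smoker, diabetic) {
  p <- structure(list(
    cohort_label = cohort_label, age_entry = age_entry, sex = sex,
    sbp_band = as.numeric(sbp_band), sbp = sbp,
    total_cholesterol_band = as.numeric(total_cholesterol_band),
    total_cholesterol = total_cholesterol,
    hdl = hdl, smoker = isTRUE(smoker), diabetic = isTRUE(diabetic)
  ), class = "irapen_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  if (!p$cohort_label %in% COHORT_LABELS) {
    .stopf("unknown cohort_label '%s'", p$cohort_label)
  }
  if (!p$sex %in% c("male", "female")) .stopf("sex must be male/female")
  if (p$age_entry < 30) .stopf("age_entry must be >= 30 (got %s)", p$age_entry)
  for (nm in c("sbp_band", "total_cholesterol_band")) {
    b <- p[[nm]]
    if (length(b) != 2L || !(b[2] > b[1])) .stopf("%s must be a non-empty interval", nm)
  }
  if (p$sbp < p$sbp_band[1] || p$sbp > p$sbp_band[2]) {
    .stopf("representative sbp %s outside band [%s, %s]", p$sbp, p$sbp_band[1], p$sbp_band[2])
  }
  tc <- p$total_cholesterol
  if (tc < p$total_cholesterol_band[1] || tc > p$total_cholesterol_band[2]) {
    .stopf("representative total_cholesterol outside its band")
  }
  if (p$hdl <= 0) .stopf("hdl must be positive")
  invisible(p)
}

#' Construct a treatment effect (per-outcome relative risks)
#'
#' @param name component name (e.g. `"statin"`, `"ace_inhibitor"`)
#' @param rr_chd,rr_stroke relative risk of a CHD / stroke event
#' @param rr_chd_ci,rr_stroke_ci 95\% confidence intervals `c(lo, hi)`
#' @return an object of class `irapen_treatment`
#' @export
treatment_effect <- function(name, rr_chd, rr_chd_ci, rr_stroke, rr_stroke_ci) {
  t <- structure(list(
    name = name,
    rr_chd = rr_chd, rr_chd_ci = as.numeric(rr_chd_ci),
    rr_stroke = rr_stroke, rr_stroke_ci = as.numeric(rr_stroke_ci)
  ), class = "irapen_treatment")
  validate_treatment(t)
  t
}

validate_treatment <- function(t) {
  for (oc in c("chd", "stroke")) {
    rr <- t[[paste0("rr_", oc)]]
    ci <- t[[paste0("rr_", oc, "_ci")]]
    if (!is.numeric(rr) || rr <= 0) .stopf("%s: rr_%s must be positive", t$name, oc)
    if (length(ci) != 2L || any(ci <= 0)) .stopf("%s: rr_%s_ci must be positive pair", t$name, oc)
    if (!(ci[1] <= rr && rr <= ci[2])) {
      .stopf("%s: rr_%s = %s outside its CI [%s, %s]", t$name, oc, rr, ci[1], ci[2])
    }
  }
  invisible(t)
}

validate_costs <- function(co) {
  num <- c("program_annual_cost", "chd_cost_year1", "chd_cost_subsequent",
           "stroke_cost_year1", "stroke_cost_subsequent",
           "status_quo_eventfree_cost", "death_cost")
  for (nm in num) {
    v <- co[[nm]]
    if (is.null(v) || !is.numeric(v) || v < 0) .stopf("costs/%s must be a non-negative number", nm)
  }
  for (nm in c("prehospital_chd_death_fraction", "fatal_stroke_cost_fraction")) {
    if (!.is_prob(co[[nm]])) .stopf("costs/%s must be in [0,1]", nm)
  }
  if (co$chd_cost_year1 < co$chd_cost_subsequent) .stopf("chd_cost_year1 < chd_cost_subsequent")
  if (co$stroke_cost_year1 < co$stroke_cost_subsequent) .stopf("stroke_cost_year1 < stroke_cost_subsequent")
  invisible(co)
}

validate_utilities <- function(u) {
  for (nm in c("u_healthy", "u_dead", "u_chd_year1", "u_chd_subsequent",
               "u_stroke_year1", "u_stroke_subsequent")) {
    if (!.is_prob(u[[nm]])) .stopf("utilities/%s must be in [0,1]", nm)
  }
  if (u$u_dead != 0) .stopf("utilities/u_dead must be exactly 0")
  if (u$u_healthy != 1) .stopf("utilities/u_healthy must be exactly 1")
  if (u$u_chd_year1 > u$u_chd_subsequent) .stopf("u_chd_year1 must be <= u_chd_subsequent")
  if (u$u_stroke_year1 > u$u_stroke_subsequent) .stopf("u_stroke_year1 must be <= u_stroke_subsequent")
  invisible(u)
}

validate_mortality <- function(m, age_entry, horizon) {
  for (nm in c("chd_case_fatality_year1", "stroke_case_fatality_year1",
               "post_chd_annual_fatality", "post_stroke_annual_fatality")) {
    if (!.is_prob(m[[nm]])) .stopf("mortality/%s must be in [0,1]", nm)
  }
  lt <- m$background_life_table
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt))) {
    .stopf("background_life_table must be a data.frame with columns age, qx")
  }
  need <- seq(age_entry, age_entry + horizon - 1)
  if (!all(need %in% lt$age)) {
    .stopf("life table must cover every age reached within the horizon (ages %d-%d)",
           min(need), max(need))
  }
  if (any(lt$qx <= 0 | lt$qx >= 1)) .stopf("life-table qx values must lie in (0,1)")
  invisible(m)
}

validate_economics <- function(e) {
  for (nm in c("discount_rate_costs", "discount_rate_effects")) {
    v <- e[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1) .stopf("economics/%s must be in [0,1)", nm)
  }
  if (e$horizon_cycles < 1) .stopf("horizon_cycles must be >= 1")
  if (!(e$adherence > 0 && e$adherence <= 1)) .stopf("adherence must be in (0,1]")
  if (e$wtp_threshold <= 0) .stopf("wtp_threshold must be positive")
  invisible(e)
}

#' Validate a full model parameter set
#'
#' Checks every type invariant and, over the whole horizon, that the annual
#' CHD probability, stroke probability and net background death probability
#' never sum to 1 or more at any age the cohort can reach.
#'
#' @param params an `irapen_params` object
#' @return `params`, invisibly; errors name the offending field
#' @export
validate_parameters <- function(params) {
  validate_profile(params$profile)
  for (t in params$treatments) validate_treatment(t)
  validate_costs(params$costs)
  validate_utilities(params$utilities)
  validate_economics(params$economics)
  validate_mortality(params$mortality, params$profile$age_entry,
                     params$economics$horizon_cycles)
  for (nm in c("annual_incidence_chd", "annual_incidence_stroke")) {
    v <- params[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1) .stopf("%s must be in [0,1)", nm)
  }
  lt <- params$mortality$background_life_table
  ages <- seq(params$profile$age_entry,
              params$profile$age_entry + params$economics$horizon_cycles - 1)
  for (a in ages) {
    base <- baseline_event_probs(params, a)
    qx <- lt$qx[match(a, lt$age)]
    if (base[["chd"]] + base[["stroke"]] + qx >= 1) {
      .stopf("event + death probabilities sum to >= 1 at age %d", a)
    }
  }
  invisible(params)
}

#' Assemble a model parameter set
#'
#' @param profile an [risk_profile()] object
#' @param treatments named list of [treatment_effect()] objects (the
#'   component library the treatment package is built from)
#' @param costs,utilities,mortality,economics parameter sub-lists; see the
#'   packaged base case for the field inventory
#' @param annual_incidence_chd,annual_incidence_stroke entry-age annual
#'   event probabilities (used directly when `risk$mode == "fixed"`)
#' @param risk risk-engine configuration: `coefficients` (see
#'   [load_risk_coefficients()]), `mode` (`"per_cycle"` recomputes the
#'   10-year risk every cycle as the cohort ages; `"fixed"` holds the
#'   entry-age incidence constant), and `chd_stroke_split` (share of CVD
#'   events that are CHD when a combined equation is used)
#' @param provenance named character vector tagging parameters as
#'   `"printed"`, `"derived"` or `"synthetic"`
#' @return a validated `irapen_params` object
#' @export
model_parameters <- function(profile, treatments, costs, utilities, mortality,
                             economics, annual_incidence_chd,
                             annual_incidence_stroke, risk = NULL,
                             provenance = character()) {
  params <- structure(list(
    profile = profile, treatments = treatments, costs = costs,
    utilities = utilities, mortality = mortality, economics = economics,
    annual_incidence_chd = annual_incidence_chd,
    annual_incidence_stroke = annual_incidence_stroke,
    risk = risk, provenance = provenance
  ), class = "irapen_params")
  validate_parameters(params)
  params
}

#' Sum cost line items exactly (integer rial arithmetic)
#'
#' The published cohort cost table lists per-item annual amounts in 2017
#' Iranian rial; the cohort total is their exact integer sum.
#'
#' @param components numeric vector of non-negative IRR amounts
#' @return the exact sum
#' @export
sum_cost_components <- function(components) {
  if (length(components) == 0L) return(0)
  if (any(components < 0)) .stopf("cost components must be non-negative")
  sum(as.numeric(components))
}

#' Inflate and convert a rial cost to US dollars
#'
#' @param base_irr cost in IRR
#' @param inflation_factor multiplicative inflation adjustment (> 0)
#' @param exchange_rate IRR per USD (> 0)
#' @return `base_irr * inflation_factor / exchange_rate`, in USD
#' @export
adjust_cost <- function(base_irr, inflation_factor, exchange_rate) {
  if (inflation_factor <= 0) .stopf("inflation_factor must be positive")
  if (exchange_rate <= 0) .stopf("exchange_rate must be positive")
  if (base_irr < 0) .stopf("base_irr must be non-negative")
  base_irr * inflation_factor / exchange_rate
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "irapen")
  if (!nzchar(path)) .stopf("packaged data file not found: %s", file)
  path
}

#' Published base-case input tables
#'
#' Returns the packaged printed parameter tables: per-cohort cost line
#' items (IRR) and model costs (USD), medication relative risks with 95\%
#' CIs, event-state costs with SEs, state utilities with SEs, economic
#' settings, case-fatality assumptions, and the eight index-cohort
#' profiles.
#'
#' @return a nested list mirroring the published tables
#' @export
base_case_tables <- function() {
  yaml::read_yaml(.extdata("base_case.yaml"))
}

.treatments_from_table <- function(tab) {
  out <- list()
  for (nm in names(tab$treatments)) {
    row <- tab$treatments[[nm]]
    out[[nm]] <- treatment_effect(nm, row$rr_chd, unlist(row$rr_chd_ci),
                                  row$rr_stroke, unlist(row$rr_stroke_ci))
  }
  out
}

.profile_from_config <- function(cfg) {
  risk_profile(
    cohort_label = cfg$cohort_label, age_entry = cfg$age_entry, sex = cfg$sex,
    sbp_band = unlist(cfg$sbp_band), sbp = cfg$sbp,
    total_cholesterol_band = unlist(cfg$total_cholesterol_band),
    total_cholesterol = cfg$total_cholesterol,
    hdl = cfg$hdl, smoker = cfg$smoker, diabetic = cfg$diabetic
  )
}

#' The packaged printed base case for one index cohort
#'
#' Assembles a full, validated parameter set for one cohort/diabetes
#' scenario. Printed items (cohort program costs, medication relative
#' risks, event-state costs, utilities, discounting, threshold, case
#' fatalities) come from the packaged tables; items the source program
#' never published (background life table, post-event annual fatalities)
#' come from the synthetic-data defaults; annual incidences are derived
#' from the cohort profile through the risk equations. The provenance map
#' tags each group accordingly.
#'
#' For the low-risk cohort without diabetes the program is screening only:
#' the treatment package is empty and the program cost is the published
#' screening-only (no-medication) cost.
#'
#' @param cohort_label one of `"low"`, `"moderate"`, `"high"`, `"very_high"`
#' @param diabetic logical scenario flag
#' @return a validated `irapen_params` object with provenance map
#' @export
paper_base_case <- function(cohort_label, diabetic) {
  if (!cohort_label %in% COHORT_LABELS) .stopf("unknown cohort label '%s'", cohort_label)
  tab <- base_case_tables()
  cohorts <- yaml::read_yaml(.extdata("index_cohorts.yaml"))
  scen <- if (diabetic) "with_diabetes" else "without_diabetes"
  profile <- .profile_from_config(cohorts[[scen]][[cohort_label]])

  prog <- tab$cohort_costs[[cohort_label]]
  program_cost <- if (diabetic) {
    prog$model_cost_usd
  } else if (cohort_label == "low") {
    # screening only, no medication
    prog$cost_without_medication_usd
  } else {
    prog$model_cost_usd - tab$diabetes_medication_annual_cost_usd[[cohort_label]]
  }

  costs <- list(
    program_annual_cost = program_cost,
    chd_cost_year1 = tab$state_costs$chd_year1$mean,
    chd_cost_subsequent = tab$state_costs$chd_subsequent$mean,
    stroke_cost_year1 = tab$state_costs$stroke_year1$mean,
    stroke_cost_subsequent = tab$state_costs$stroke_subsequent$mean,
    cost_se = list(
      chd_cost_year1 = tab$state_costs$chd_year1$se,
      chd_cost_subsequent = tab$state_costs$chd_subsequent$se,
      stroke_cost_year1 = tab$state_costs$stroke_year1$se,
      stroke_cost_subsequent = tab$state_costs$stroke_subsequent$se,
      program_annual_cost = 0.1 * program_cost  # SE fallback: 0.1 x mean
    ),
    prehospital_chd_death_fraction = tab$fatalities$prehospital_chd_death_fraction,
    fatal_stroke_cost_fraction = tab$fatalities$fatal_stroke_cost_fraction,
    status_quo_eventfree_cost = 0,
    death_cost = 0,
    currency = "USD"
  )

  u <- tab$utilities
  utilities <- list(
    u_healthy = 1, u_dead = 0,
    u_chd_year1 = u$chd_year1$mean, u_chd_subsequent = u$chd_subsequent$mean,
    u_stroke_year1 = u$stroke_year1$mean, u_stroke_subsequent = u$stroke_subsequent$mean,
    se = list(u_chd_year1 = u$chd_year1$se, u_chd_subsequent = u$chd_subsequent$se,
              u_stroke_year1 = u$stroke_year1$se, u_stroke_subsequent = u$stroke_subsequent$se)
  )

  econ <- list(
    discount_rate_costs = tab$economics$discount_rate,
    discount_rate_effects = tab$economics$discount_rate,
    horizon_cycles = tab$economics$horizon_cycles,
    cycle_length = 1, half_cycle_correction = FALSE,
    wtp_threshold = tab$economics$wtp_threshold,
    adherence = 1
  )

  coeffs <- load_risk_coefficients()
  synth <- synthetic_defaults(profile$age_entry, econ$horizon_cycles)

  mortality <- list(
    chd_case_fatality_year1 = tab$fatalities$chd_case_fatality_year1,
    stroke_case_fatality_year1 = tab$fatalities$stroke_case_fatality_year1,
    post_chd_annual_fatality = synth$post_chd_annual_fatality,
    post_stroke_annual_fatality = synth$post_stroke_annual_fatality,
    background_life_table = synth$background_life_table
  )

  p10 <- ten_year_risk(profile, coeffs)
  split <- coeffs$chd_stroke_split
  p1 <- annual_probability(p10)

  provenance <- c(
    "costs/program_annual_cost" = if (diabetic) "printed" else "derived",
    "costs/state_costs" = "printed", "utilities" = "printed",
    "treatments" = "printed", "economics" = "printed",
    "mortality/chd_case_fatality_year1" = "printed",
    "mortality/stroke_case_fatality_year1" = "printed",
    "mortality/post_chd_annual_fatality" = "synthetic",
    "mortality/post_stroke_annual_fatality" = "synthetic",
    "mortality/background_life_table" = "synthetic",
    "annual_incidence_chd" = "derived",
    "annual_incidence_stroke" = "derived"
  )

  model_parameters(
    profile = profile,
    treatments = .treatments_from_table(tab),
    costs = costs, utilities = utilities, mortality = mortality,
    economics = econ,
    annual_incidence_chd = p1 * split,
    annual_incidence_stroke = p1 * (1 - split),
    risk = list(coefficients = coeffs, mode = "per_cycle",
                chd_stroke_split = split),
    provenance = provenance
  )
}

# ---- config I/O -----------------------------------------------------------

.params_to_plain <- function(params) {
  x <- unclass(params)
  x$profile <- unclass(x$profile)
  x$treatments <- lapply(x$treatments, unclass)
  lt <- x$mortality$background_life_table
  x$mortality$background_life_table <- list(age = lt$age, qx = lt$qx)
  if (!is.null(x$risk)) x$risk$coefficients <- unclass(x$risk$coefficients)
  x$provenance <- as.list(x$provenance)
  x
}

.params_from_plain <- function(x) {
  profile <- .profile_from_config(x$profile)
  treatments <- lapply(x$treatments, function(t) {
    treatment_effect(t$name, t$rr_chd, unlist(t$rr_chd_ci),
                     t$rr_stroke, unlist(t$rr_stroke_ci))
  })
  lt <- x$mortality$background_life_table
  x$mortality$background_life_table <-
    data.frame(age = unlist(lt$age), qx = unlist(lt$qx))
  risk <- x$risk
  if (!is.null(risk)) {
    risk$coefficients <- structure(risk$coefficients, class = "irapen_risk_coeffs")
  }
  model_parameters(
    profile = profile, treatments = treatments, costs = x$costs,
    utilities = x$utilities, mortality = x$mortality, economics = x$economics,
    annual_incidence_chd = x$annual_incidence_chd,
    annual_incidence_stroke = x$annual_incidence_stroke,
    risk = risk, provenance = unlist(x$provenance)
  )
}

#' Load a model parameter set from a YAML or JSON config file
#'
#' Missing optional sections are filled from the packaged base case for
#' the config's cohort/diabetes scenario. The loaded set must pass the
#' full validation suite; violations are reported naming the field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config
#' @return a validated `irapen_params` object
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) .stopf("YAML parse error in %s: %s", path, conditionMessage(e)))
  } else if (ext == "json") {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
             error = function(e) .stopf("JSON parse error in %s: %s", path, conditionMessage(e)))
  } else {
    .stopf("unsupported config extension '.%s' (use yaml or json)", ext)
  }
  # fill omitted sections from the packaged base case
  label <- raw$profile$cohort_label
  diabetic <- isTRUE(raw$profile$diabetic)
  if (is.null(label)) .stopf("config must specify profile/cohort_label")
  base <- .params_to_plain(paper_base_case(label, diabetic))
  merged <- modifyList(base, raw)
  .params_from_plain(merged)
}

#' Serialize a model parameter set to JSON
#'
#' Full-precision decimal text; `load_parameters()` of the written file
#' reproduces the object exactly.
#'
#' @param params an `irapen_params` object
#' @param path output path (`.json`)
#' @export
save_parameters <- function(params, path) {
  jsonlite::write_json(.params_to_plain(params), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a background life table from a two-column CSV
#'
#' @param path CSV with columns `age` and `qx` (annual death probability)
#' @return a data.frame with columns `age`, `qx`
#' @export
load_life_table_csv <- function(path) {
  lt <- read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) .stopf("life table CSV needs columns age, qx")
  if (any(lt$qx <= 0 | lt$qx >= 1)) .stopf("life-table qx values must lie in (0,1)")
  lt[, c("age", "qx")]
}
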