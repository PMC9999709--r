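# One-way deterministic sensitivity analysis: vary each uncertain
# parameter to its bounds one at a time and rank by ICER spread for the
# tornado diagram.

#' Build a one-way sensitivity spec
#'
#' @param path slash-path into the parameter tree (see [param_get()])
#' @param low,high bound values; the base value must lie between them
#' @param provenance `"ci95"`, `"adherence_range"` or `"manual"`
#' @return an `irapen_dsa_spec`
#' @export
dsa_spec <- function(path, low, high, provenance = "manual") {
  if (low > high) .stopf("%s: low bound exceeds high bound", path)
  structure(list(path = path, low = low, high = high, provenance = provenance),
            class = "irapen_dsa_spec")
}

#' Default one-way sensitivity specs for a parameter set
#'
#' Covers every treatment component's per-outcome relative risk at its
#' published 95\% CI, each cost item at mean +/- 1.96 SE (truncated at 0),
#' each event-state utility at mean +/- 1.96 SE (truncated to `[0, 1]`),
#' and adherence over 50-100%. Only components actually in the cohort's
#' treatment package get RR specs.
#'
#' @param params a validated `irapen_params` object
#' @return list of [dsa_spec()] objects
#' @export
default_dsa_specs <- function(params) {
  specs <- list()
  pkg <- build_package(params$profile$cohort_label, params$profile$diabetic,
                       treatments = params$treatments)
  for (t in pkg$components) {
    for (oc in c("chd", "stroke")) {
      ci <- t[[paste0("rr_", oc, "_ci")]]
      specs[[length(specs) + 1L]] <-
        dsa_spec(sprintf("treatments/%s/rr_%s", t$name, oc), ci[1], ci[2], "ci95")
    }
  }
  for (nm in c("program_annual_cost", "chd_cost_year1", "chd_cost_subsequent",
               "stroke_cost_year1", "stroke_cost_subsequent")) {
    mean <- params$costs[[nm]]
    se <- params$costs$cost_se[[nm]]
    if (is.null(se)) se <- 0.1 * mean  # SE fallback rule
    specs[[length(specs) + 1L]] <-
      dsa_spec(paste0("costs/", nm), max(mean - 1.96 * se, 0), mean + 1.96 * se, "ci95")
  }
  for (nm in c("u_chd_year1", "u_chd_subsequent", "u_stroke_year1", "u_stroke_subsequent")) {
    mean <- params$utilities[[nm]]
    se <- params$utilities$se[[nm]]
    specs[[length(specs) + 1L]] <-
      dsa_spec(paste0("utilities/", nm),
               max(mean - 1.96 * se, 0), min(mean + 1.96 * se, 1), "ci95")
  }
  specs[[length(specs) + 1L]] <-
    dsa_spec("economics/adherence", 0.5, 1.0, "adherence_range")
  specs
}

.icer_at <- function(params, path, value) {
  run_cea(param_set(params, path, value))
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model twice per spec (parameter at its low and high
#' bound, everything else at base) and orders parameters by the absolute
#' ICER spread. Entries whose ICER is undefined at either bound are
#' flagged and excluded from the spread ordering. Spreads are measured on
#' full-precision ICERs, not the rounded reported values.
#'
#' @param params a validated `irapen_params` object
#' @param specs list of [dsa_spec()]s; default [default_dsa_specs()]
#' @return data.frame (class `irapen_tornado`): `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `spread`, `undefined` flag;
#'   sorted by spread descending with undefined entries last. The
#'   base-case ICER is attached as attribute `base_icer`.
#' @export
run_one_way <- function(params, specs = default_dsa_specs(params)) {
  base_value <- function(path) param_get(params, path)
  for (sp in specs) {
    b <- base_value(sp$path)
    if (!(sp$low <= b && b <= sp$high)) {
      .stopf("%s: base value %g outside [%g, %g]", sp$path, b, sp$low, sp$high)
    }
  }
  base_res <- run_cea(params)
  rows <- lapply(specs, function(sp) {
    lo <- .icer_at(params, sp$path, sp$low)
    hi <- .icer_at(params, sp$path, sp$high)
    undef <- is.na(lo$icer) || is.na(hi$icer)
    data.frame(parameter = sp$path, low = sp$low, high = sp$high,
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               spread = if (undef) NA_real_ else abs(hi$icer - lo$icer),
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$undefined, -ifelse(is.na(out$spread), -Inf, out$spread)), ]
  rownames(out) <- NULL
  class(out) <- c("irapen_tornado", "data.frame")
  attr(out, "base_icer") <- base_res$icer
  out
}

#' Write tornado results to CSV
#'
#' @param tornado an `irapen_tornado` from [run_one_way()]
#' @param path output CSV path
#' @export
export_tornado <- function(tornado, path) {
  write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}
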