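# Pairwise incremental cost-effectiveness analysis: ICER, dominance
# classification, net monetary benefit.

#' Incremental cost-effectiveness of the intervention vs the comparator
#'
#' @param ref_arm outcomes list for the reference arm (needs `cost`,
#'   `qaly`, `ly` — e.g. from [run_arm()] or printed table rows)
#' @param comp_arm outcomes list for the comparison (intervention) arm
#' @param threshold willingness-to-pay per QALY, USD
#' @param zero_tol QALY difference below which the ICER is undefined
#' @return an `irapen_ce_result`: per-arm outcomes, `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer` (full precision; `NA` when
#'   undefined), `icer_reported` (rounded to whole dollars), `status` in
#'   `{icer, dominant_cost_saving, dominated, undefined_zero_effect}`, and
#'   `nmb = threshold * delta_qaly - delta_cost`
#' @export
incremental <- function(ref_arm, comp_arm, threshold, zero_tol = 1e-9) {
  stopifnot(is.finite(ref_arm$cost), is.finite(comp_arm$cost),
            is.finite(ref_arm$qaly), is.finite(comp_arm$qaly))
  dc <- comp_arm$cost - ref_arm$cost
  dq <- comp_arm$qaly - ref_arm$qaly
  dly <- if (!is.null(ref_arm$ly) && !is.null(comp_arm$ly)) comp_arm$ly - ref_arm$ly else NA_real_
  nmb <- threshold * dq - dc

  if (abs(dq) < zero_tol) {
    status <- "undefined_zero_effect"
    icer <- NA_real_
  } else {
    icer <- dc / dq
    status <- if (dc < 0 && dq > 0) {
      "dominant_cost_saving"
    } else if (dc > 0 && dq < 0) {
      "dominated"
    } else {
      if (dc < 0 && dq < 0) {
        warning("southwest quadrant (less costly, less effective); ",
                "ICER reported raw with dominated-direction caveat", call. = FALSE)
      }
      "icer"
    }
  }
  structure(list(
    ref = ref_arm[c("cost", "qaly", "ly")],
    comp = comp_arm[c("cost", "qaly", "ly")],
    delta_cost = dc, delta_qaly = dq, delta_ly = dly,
    icer = icer, icer_reported = if (is.na(icer)) NA_real_ else round(icer),
    status = status, threshold = threshold, nmb = nmb
  ), class = "irapen_ce_result")
}

#' Classify a cost-effectiveness result against a threshold
#'
#' @param result an `irapen_ce_result` (or a bare ICER number)
#' @param threshold willingness-to-pay per QALY, USD (> 0)
#' @return one of `"cost_saving"`, `"cost_effective"`,
#'   `"not_cost_effective"`, `"undefined"`
#' @export
classify_against_threshold <- function(result, threshold) {
  if (threshold <= 0) .stopf("threshold must be positive")
  if (inherits(result, "irapen_ce_result")) {
    if (result$status == "undefined_zero_effect") return("undefined")
    if (result$status == "dominant_cost_saving") return("cost_saving")
    icer <- result$icer
  } else {
    icer <- result
    if (is.na(icer)) return("undefined")
    if (icer < 0) return("cost_saving")
  }
  if (icer >= 0 && icer <= threshold) "cost_effective" else "not_cost_effective"
}

#' Run both arms and compare them
#'
#' @param params a validated `irapen_params` object
#' @return an `irapen_ce_result` with `$arms` holding the two [run_arm()]
#'   outputs
#' @export
run_cea <- function(params) {
  sq <- run_arm(params, "status_quo")
  ir <- run_arm(params, "irapen")
  res <- incremental(sq, ir, params$economics$wtp_threshold)
  res$arms <- list(status_quo = sq, irapen = ir)
  res$cohort_label <- params$profile$cohort_label
  res$diabetic <- params$profile$diabetic
  res
}

#' Tabulate a CE result in the three-row layout (status quo / intervention
#' / incremental)
#'
#' Undiscounted life years are shown alongside discounted QALYs, matching
#' the conventional reporting layout. ICER is reported to whole dollars;
#' `"Undefined"` when the QALY difference is zero.
#'
#' @param result an `irapen_ce_result` from [run_cea()]
#' @param digits_effect decimal places for QALY/LY cells
#' @return a data.frame with rows status_quo / irapen / incremental
#' @export
ce_table <- function(result, digits_effect = 2) {
  arms <- result$arms
  if (is.null(arms)) .stopf("ce_table needs a result from run_cea()")
  ly <- c(arms$status_quo$ly_undiscounted, arms$irapen$ly_undiscounted)
  icer_cell <- if (result$status == "undefined_zero_effect") {
    "Undefined"
  } else {
    sprintf("%s$%d", if (result$icer_reported < 0) "-" else "", abs(result$icer_reported))
  }
  data.frame(
    row = c("status_quo", "irapen", "incremental"),
    cost = round(c(arms$status_quo$cost, arms$irapen$cost, result$delta_cost)),
    qaly = round(c(arms$status_quo$qaly, arms$irapen$qaly, result$delta_qaly), digits_effect),
    ly = round(c(ly, ly[2] - ly[1]), digits_effect),
    icer = c("", "", icer_cell),
    stringsAsFactors = FALSE
  )
}

#' @export
print.irapen_ce_result <- function(x, ...) {
  cat("Incremental cost-effectiveness result\n")
  cat(sprintf("  delta cost: $%.2f   delta QALY: %.4f   delta LY: %s\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$delta_ly)) "NA" else sprintf("%.4f", x$delta_ly)))
  cat(sprintf("  status: %s", x$status))
  if (!is.na(x$icer)) cat(sprintf("   ICER: $%d/QALY", x$icer_reported))
  cat(sprintf("\n  NMB at $%s/QALY: $%.2f\n", format(x$threshold, big.mark = ","), x$nmb))
  invisible(x)
}
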