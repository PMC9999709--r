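# Run manifests and file-based reports used by the analysis scripts.

#' Write a run manifest
#'
#' Records the command, inputs, seed, package version and parameter
#' provenance next to a run's outputs so deterministic runs can be
#' reproduced bit-identically.
#'
#' @param out_dir output directory (created if missing)
#' @param command short name of the run (e.g. `"base_case"`, `"psa"`)
#' @param seed RNG seed used, or `NA` for deterministic runs
#' @param params the parameter set used (its provenance map is embedded)
#' @param extra named list of additional fields
#' @return path of the written manifest JSON, invisibly
#' @export
write_run_manifest <- function(out_dir, command, seed = NA, params = NULL,
                               extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    command = command,
    seed = seed,
    package_version = as.character(packageVersion("irapen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = if (!is.null(params)) as.list(params$provenance)
  ), extra)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Run one cohort end to end and write its report files
#'
#' Writes both arms' cohort traces, the three-row CE table as CSV, the
#' full-precision result as JSON, and a manifest.
#'
#' @param params a validated `irapen_params` object
#' @param out_dir output directory
#' @param label file-name stem (defaults to cohort label + diabetes flag)
#' @return the `irapen_ce_result`, invisibly
#' @export
run_report <- function(params, out_dir, label = NULL) {
  if (is.null(label)) {
    label <- paste0(params$profile$cohort_label,
                    if (params$profile$diabetic) "_diabetes" else "_no_diabetes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_cea(params)
  export_trace(res$arms$status_quo$trace,
               file.path(out_dir, paste0(label, "_trace_status_quo.csv")))
  export_trace(res$arms$irapen$trace,
               file.path(out_dir, paste0(label, "_trace_irapen.csv")))
  write.csv(ce_table(res), file.path(out_dir, paste0(label, "_ce_table.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
         delta_ly = res$delta_ly, icer = res$icer, status = res$status,
         nmb = res$nmb, threshold = res$threshold,
         classification = classify_against_threshold(res, res$threshold)),
    file.path(out_dir, paste0(label, "_result.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  write_run_manifest(out_dir, paste0("run_", label), seed = NA, params = params)
  invisible(res)
}

#' Printed base-case result rows packaged with the model
#'
#' The published three-row (status quo / intervention / incremental)
#' result tables for the eight cohort scenarios plus the sex
#' heterogeneity runs, as printed: costs in whole USD, QALYs/LYs to two
#' decimals, ICER cells as printed (including the undefined low-risk
#' cell). Used as inputs for arithmetic cross-checks, never as values the
#' model is tuned toward.
#'
#' @return data.frame with columns `table`, `cohort`, `sex`, `row`,
#'   `cost`, `qaly`, `ly`, `icer`
#' @export
printed_results <- function() {
  read.csv(.extdata("printed_results.csv"), stringsAsFactors = FALSE)
}
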