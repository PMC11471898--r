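## Machine-readable JSON report shared by all stages. Numbers are written
## at full precision (digits = NA) so a written report parses back to
## bit-identical values; key order is fixed so reruns are byte-identical.

REPORT_SCHEMA_VERSION <- "1.0"

#' Assemble (and optionally write) the analysis report
#'
#' @param attributions A `partition_result`, or `NULL`/empty list when no
#'   partition was run.
#' @param summaries Named list of `treatment_summary` objects (may be
#'   empty).
#' @param qc Named list of QC flags and notes (e.g. qPCR verdicts, the
#'   dissolved-N2O limitation flag).
#' @param path Optional output path; when given the report is written as
#'   JSON.
#' @param metrics Optional [group_metrics()] data frame.
#' @param abundance Optional [correlate_abundance()] data frame.
#' @param seed Seed recorded in the report (NA when no randomness was
#'   used).
#' @return The report list, invisibly when written.
#' @export
write_report <- function(attributions = NULL, summaries = list(), qc = list(),
                         path = NULL, metrics = NULL, abundance = NULL,
                         seed = NA) {
  summ_df <- if (length(summaries)) {
    do.call(rbind, lapply(summaries, function(s) data.frame(
      treatment = s$treatment,
      nitrification_rate = s$nitrification_rate,
      rate_raw = s$rate_raw, rate_se = s$rate_se,
      n2o_cumulative = s$n2o_cumulative, n2o_se = s$n2o_se,
      n_replicates = s$n_replicates, low_support = s$low_support)))
  } else data.frame()
  part <- if (inherits(attributions, "partition_result")) {
    list(attributions = attributions$attributions,
         total_n2o = attributions$total_n2o,
         ao_attributed_pct = attributions$ao_attributed_pct,
         non_ao_pct = attributions$non_ao_pct,
         clamped_groups = as.list(attributions$clamped_groups),
         residual_after_clamp = attributions$residual_after_clamp,
         fully_resolved = attributions$fully_resolved,
         intervals = if (!is.null(attributions$intervals))
           attributions$intervals else NULL)
  } else list(attributions = data.frame())
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("nitropart")),
    seed = seed,
    treatments = summ_df,
    partition = part,
    metrics = if (is.null(metrics)) data.frame() else metrics,
    abundance = if (is.null(abundance)) data.frame() else abundance,
    qc = qc
  )
  if (!is.null(path)) {
    ## 17 significant digits: every double round-trips bit-exactly
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Read a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return The report as nested lists/data frames; numeric fields round-
#'   trip at full precision.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
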