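## End-to-end orchestration: headspace conversion -> kinetics -> inhibitor
## partition -> per-group metrics, with optional qPCR and abundance
## stages. Configured from a list or YAML file; fully scriptable, all
## randomness from one seed, so a rerun with the same config and seed
## writes byte-identical reports.

#' Run the full partitioning pipeline
#'
#' Stages, in order: load the design and measurements, convert headspace
#' mixing ratios to N2O mass, summarise each treatment (rates and
#' cumulative emissions), partition among AOA/AOB/CMX/non-AO (with
#' bootstrap intervals when `bootstrap > 0`), quantify amoA copies from a
#' qPCR table and derive yields and cell-specific rates, correlate
#' abundance series with covariates. Any stage failure raises an error
#' naming the stage.
#'
#' @param config Named list or path to a YAML file with entries:
#'   \describe{
#'     \item{measurements}{CSV path (required).}
#'     \item{design}{YAML path or a `microcosm_design` (default design
#'       when absent).}
#'     \item{qpcr}{qPCR CSV path (optional; required when `metrics` is
#'       TRUE).}
#'     \item{abundance, covariates}{CSV paths (optional, both or
#'       neither).}
#'     \item{metrics}{Compute group metrics (default TRUE when `qpcr`
#'       given).}
#'     \item{bootstrap}{Bootstrap resamples, 0 to skip (default 0).}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{strict_loq}{Suppress cell-specific rates for below-LOQ
#'       copies (default FALSE).}
#'     \item{out_dir}{Output directory; when given, `report.json` and
#'       `summary.txt` are written there.}
#'   }
#' @return The report list (see [write_report()]), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  want_metrics <- isTRUE(config$metrics) ||
    (is.null(config$metrics) && !is.null(config$qpcr))
  if (want_metrics && is.null(config$qpcr))
    stop("pipeline stage 'metrics' failed: group metrics requested but no 'qpcr' table configured")

  design <- stage("design", {
    if (is.null(config$design)) microcosm_design()
    else if (inherits(config$design, "microcosm_design")) {
      v <- validate_design(config$design)
      if (length(v)) stop(paste(v, collapse = "; "))
      config$design
    } else read_design(config$design)
  })
  table <- stage("measurements", {
    if (is.null(config$measurements)) stop("no 'measurements' file configured")
    load_measurements(config$measurements, design)
  })
  table <- stage("headspace", add_n2o_mass(table, design))
  summaries <- stage("kinetics", summarize_all_treatments(table, design))
  n_boot <- if (is.null(config$bootstrap)) 0 else as.integer(config$bootstrap)
  part <- stage("partition", {
    if (n_boot > 0) propagate_uncertainty(table, design, n_boot = n_boot, seed = seed)
    else partition(summaries, design$inhibitor_scheme)
  })

  qc <- list(dissolved_n2o_ignored = TRUE)
  metrics <- NULL
  if (want_metrics) {
    mstage <- stage("metrics", {
      qres <- quantify_qpcr_table(config$qpcr)
      copies <- lapply(qres, function(x) x$estimate)
      copies <- copies[!vapply(copies, is.null, logical(1))]
      list(metrics = group_metrics(part, copies,
                                   duration_h = design$incubation_duration,
                                   strict_loq = isTRUE(config$strict_loq)),
           qpcr_qc = lapply(qres, function(x) list(
             efficiency = x$curve$efficiency,
             r_squared = x$curve$r_squared,
             qc_pass = x$curve$qc_pass)))
    })
    metrics <- mstage$metrics
    qc$qpcr <- mstage$qpcr_qc
  }
  abundance <- NULL
  if (!is.null(config$abundance)) {
    abundance <- stage("abundance", {
      if (is.null(config$covariates))
        stop("abundance table given without a 'covariates' table")
      ab <- utils::read.csv(config$abundance, stringsAsFactors = FALSE)
      cv <- utils::read.csv(config$covariates, stringsAsFactors = FALSE)
      correlate_abundance(ab, cv)
    })
  }

  qc$config_hash <- config_hash(config)
  report <- write_report(part, summaries, qc, metrics = metrics,
                         abundance = abundance, seed = seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    writeLines(c(utils::capture.output(print(part)),
                 "", sprintf("seed: %d | config: %s | nitropart %s",
                             seed, qc$config_hash,
                             as.character(utils::packageVersion("nitropart")))),
               file.path(config$out_dir, "summary.txt"))
  }
  invisible(report)
}

## Deterministic fingerprint of the (path-valued) config for the run log.
config_hash <- function(config) {
  config$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}
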