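## Measurement tables: replicated analyte time series from destructive
## microcosm sampling. Canonical units are fixed per analyte:
##   NH4_N    ug N g^-1 (KCl-extractable ammonium)
##   N2O_ppb  headspace mixing ratio, ppb v/v
##   N2O_mass ng N2O-N g^-1 (derived from N2O_ppb via the ideal-gas law)

ANALYTES <- c("NH4_N", "N2O_ppb", "N2O_mass")

#' Assemble a validated measurement table
#'
#' @param df Data frame with columns `treatment`, `replicate`, `time_h`,
#'   `analyte`, `value`.
#' @param design A [microcosm_design()]; treatments are restricted to the
#'   names in its inhibitor scheme.
#' @return The data frame with class `measurement_table`, rows ordered by
#'   (treatment, analyte, time, replicate) so equal contents compare equal
#'   regardless of input row order.
#' @export
measurement_table <- function(df, design) {
  needed <- c("treatment", "replicate", "time_h", "analyte", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[needed]
  df$treatment <- as.character(df$treatment)
  df$analyte <- as.character(df$analyte)
  df$replicate <- as.integer(df$replicate)
  df$time_h <- as.numeric(df$time_h)
  df$value <- as.numeric(df$value)

  known <- names(design$inhibitor_scheme)
  bad_trt <- which(!(df$treatment %in% known))
  if (length(bad_trt))
    stop(sprintf("schema error: row %d has unknown treatment '%s' (design declares: %s)",
                 bad_trt[1], df$treatment[bad_trt[1]], paste(known, collapse = ", ")))
  bad_an <- which(!(df$analyte %in% ANALYTES))
  if (length(bad_an))
    stop(sprintf("schema error: row %d has unknown analyte '%s' (expected one of: %s)",
                 bad_an[1], df$analyte[bad_an[1]], paste(ANALYTES, collapse = ", ")))
  neg <- which(!is.finite(df$value) | df$value < 0)
  if (length(neg))
    stop(sprintf("validation error: row %d has negative or non-finite value (%s)",
                 neg[1], format(df$value[neg[1]])))
  key <- paste(df$treatment, df$replicate, df$time_h, df$analyte, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate key at row %d: treatment=%s replicate=%d time_h=%g analyte=%s",
                 dup[1], df$treatment[dup[1]], df$replicate[dup[1]],
                 df$time_h[dup[1]], df$analyte[dup[1]]))
  for (trt in unique(df$treatment)) {
    sub <- df[df$treatment == trt, ]
    if (length(unique(sub$time_h)) < 2)
      stop(sprintf("treatment '%s' has fewer than 2 timepoints", trt))
  }
  df <- df[order(df$treatment, df$analyte, df$time_h, df$replicate), ]
  rownames(df) <- NULL
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Load microcosm measurements from CSV
#'
#' Expects header columns `treatment,replicate,time_h,analyte,value` in the
#' canonical units (see [measurement_table()]). Unknown treatments or
#' analytes, duplicate keys and negative values are rejected with an error
#' naming the offending row.
#'
#' @param path CSV file path.
#' @inheritParams measurement_table
#' @return A `measurement_table`.
#' @export
load_measurements <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  measurement_table(df, design)
}

#' Write a measurement table to CSV
#'
#' @param table A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Pull one analyte series for one treatment as a plain data frame.
analyte_series <- function(table, treatment, analyte) {
  sub <- table[table$treatment == treatment & table$analyte == analyte, , drop = FALSE]
  as.data.frame(sub)
}
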