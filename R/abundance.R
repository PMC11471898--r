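## Relative-abundance formulas for metagenomic markers and MAGs, temporal
## fold changes, and correlations of abundance series with environmental
## covariates (EPS polysaccharide/protein, seawater NH4+).

#' Length-normalised amoA relative abundance
#'
#' Mapped reads divided by gene length; optionally further normalised by
#' the sample's total mapped reads to compare across sequencing depths.
#'
#' @param mapped_reads Read count(s) mapped to the gene.
#' @param gene_length_bp Gene length(s) in bp (> 0).
#' @param total_mapped_reads Optional per-sample total for depth
#'   normalisation.
#' @return Reads per bp (per total read when `total_mapped_reads` given).
#' @export
amoa_relative_abundance <- function(mapped_reads, gene_length_bp,
                                    total_mapped_reads = NULL) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0")
  x <- mapped_reads / gene_length_bp
  if (!is.null(total_mapped_reads)) {
    if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
    x <- x / total_mapped_reads
  }
  x
}

#' MAG relative abundance from contig coverages
#'
#' Total coverage of the MAG's contigs over the total coverage of all
#' contigs in the sample, times 100. Over a disjoint partition of the
#' contigs the percentages sum to exactly 100.
#'
#' @param mag_contig_coverages Coverages of the contigs binned into the
#'   MAG.
#' @param total_coverage_all_contigs Summed coverage of every contig
#'   (> 0).
#' @return Relative abundance in percent.
#' @export
mag_relative_abundance <- function(mag_contig_coverages,
                                   total_coverage_all_contigs) {
  if (total_coverage_all_contigs <= 0) stop("total coverage must be > 0")
  if (any(mag_contig_coverages < 0)) stop("coverages must be >= 0")
  100 * sum(mag_contig_coverages) / total_coverage_all_contigs
}

#' Fold change between two abundances
#'
#' @param value_early Earlier value (> 0).
#' @param value_late Later value (>= 0).
#' @return List: `fold` (`value_late / value_early`) and `undefined`
#'   (TRUE when the early value is 0, in which case `fold` is `NA`).
#' @examples
#' fold_change(0.02, 0.7)$fold  # 35
#' @export
fold_change <- function(value_early, value_late) {
  if (value_early < 0 || value_late < 0) stop("abundances must be >= 0")
  if (value_early == 0) return(list(fold = NA_real_, undefined = TRUE))
  list(fold = value_late / value_early, undefined = FALSE)
}

#' Pearson correlation with a t-based two-sided p value
#'
#' @param x,y Numeric series of equal length >= 3, finite, each with
#'   nonzero variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one of the series")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate abundance series with environmental covariates
#'
#' Pairs each entity's abundance at each sampling month with the covariate
#' observed the same month (no lagging), one Pearson test per
#' entity-covariate pair. Entities listed in `pool` are summed into a
#' combined series first (e.g. the two comammox MAGs). Raw p values are
#' reported; a Benjamini-Hochberg column is appended when `adjust = TRUE`.
#'
#' @param abundance Data frame `entity, month, value`.
#' @param covariates Data frame with a `month` column plus one column per
#'   covariate (e.g. `PS`, `PN`, `NH4`).
#' @param pool Optional named list: name -> character vector of entities to
#'   sum into a pooled series.
#' @param adjust Append BH-adjusted p values (default FALSE; raw p is the
#'   primary display).
#' @return Data frame: `entity`, `covariate`, `r`, `p`, `n` (and `p_adj`).
#' @export
correlate_abundance <- function(abundance, covariates, pool = NULL,
                                adjust = FALSE) {
  stopifnot(all(c("entity", "month", "value") %in% names(abundance)),
            "month" %in% names(covariates))
  if (!is.null(pool)) {
    for (nm in names(pool)) {
      sub <- abundance[abundance$entity %in% pool[[nm]], ]
      agg <- stats::aggregate(value ~ month, sub, sum)
      agg$entity <- nm
      abundance <- rbind(abundance, agg[c("entity", "month", "value")])
    }
  }
  cov_names <- setdiff(names(covariates), "month")
  rows <- list()
  for (e in unique(abundance$entity)) {
    sub <- abundance[abundance$entity == e, ]
    sub <- stats::aggregate(value ~ month, sub, mean)  # mean per month
    m <- merge(sub, covariates, by = "month")
    for (cv in cov_names) {
      pc <- pearson_correlation(m$value, m[[cv]])
      rows[[length(rows) + 1]] <- data.frame(entity = e, covariate = cv,
                                             r = pc$r, p = pc$p, n = pc$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
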