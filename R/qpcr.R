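## qPCR standard-curve fitting and amoA copy quantification. Cq is linear
## in log10 template copies; a 10-fold dilution series with perfect
## doubling per cycle gives slope -1/log10(2) = -3.3219 and efficiency 1.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 copies. Amplification efficiency
#' is `10^(-1/slope) - 1`; the curve passes QC when R^2 exceeds `min_r2`
#' and the efficiency lies inside `efficiency_band`.
#'
#' @param log10_copies log10 template copies of the standards (>= 3
#'   distinct dilution levels).
#' @param cq Quantification cycles, same length.
#' @param min_r2 QC floor for R^2 (default 0.98).
#' @param efficiency_band Two-element acceptance band for efficiency as a
#'   fraction (default `c(0.90, 1.05)`).
#' @return A `standard_curve` list: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n_points`, `qc_pass`, `qc_notes`.
#' @examples
#' sc <- fit_standard_curve(7:3, 10 + 3.3219 * (7 - (7:3)))
#' sc$efficiency  # 1 (100%)
#' @export
fit_standard_curve <- function(log10_copies, cq, min_r2 = 0.98,
                               efficiency_band = c(0.90, 1.05)) {
  stopifnot(length(log10_copies) == length(cq))
  if (length(unique(log10_copies)) < 3)
    stop("need >= 3 distinct dilution levels")
  if (stats::var(log10_copies) == 0) stop("zero variance in log10 copies")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ## R^2 from sums of squares directly (summary.lm warns on perfect fits)
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  efficiency <- 10^(-1 / slope) - 1
  notes <- character(0)
  if (!(slope < 0)) notes <- c(notes, "non-negative slope: Cq must fall as template rises")
  if (r2 <= min_r2) notes <- c(notes, sprintf("R^2 %.4f <= %.2f", r2, min_r2))
  if (is.finite(efficiency) &&
      (efficiency < efficiency_band[1] || efficiency > efficiency_band[2]))
    notes <- c(notes, sprintf("efficiency %.1f%% outside [%g%%, %g%%]",
                              100 * efficiency, 100 * efficiency_band[1],
                              100 * efficiency_band[2]))
  structure(list(
    slope = slope, intercept = intercept, r_squared = r2,
    efficiency = efficiency, n_points = length(cq),
    qc_pass = length(notes) == 0, qc_notes = notes
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.1f%%, R^2 %.4f, %d points, QC %s\n",
              100 * x$efficiency, x$r_squared, x$n_points,
              if (x$qc_pass) "pass" else paste("FAIL:", paste(x$qc_notes, collapse = "; "))))
  invisible(x)
}

#' Quantify a sample from its Cq
#'
#' Inverts the standard curve, `copies = 10^((cq - intercept)/slope)`, and
#' scales from per-reaction to per-gram. Estimates below the limit of
#' quantification are flagged but retained, never zeroed: downstream
#' cell-specific rates must not divide by artificial zeros.
#'
#' @param cq Quantification cycle(s); technical replicates are averaged
#'   (mean Cq) before inversion unless `per_replicate = TRUE`.
#' @param curve A `standard_curve`.
#' @param scale Reaction-to-per-gram factor (copies g^-1 per copies
#'   reaction^-1): elution volume / (template volume x sample mass), > 0.
#' @param loq Limit of quantification in copies g^-1 (default 1e2).
#' @param assay Optional assay label (`"AOA"`, `"AOB"`, `"CMX"`).
#' @param override_qc Quantify even from a failed curve; the estimate is
#'   then flagged `qc_overridden`.
#' @param per_replicate Return one estimate per Cq instead of averaging.
#' @return A `copy_estimate` list (`copies_per_g`, `below_loq`, `assay`,
#'   `qc_overridden`), or a list of them when `per_replicate = TRUE`.
#' @export
quantify_sample <- function(cq, curve, scale, loq = 1e2, assay = NA_character_,
                            override_qc = FALSE, per_replicate = FALSE) {
  if (any(!is.finite(cq))) stop("non-finite Cq")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (!curve$qc_pass && !override_qc)
    stop("standard curve failed QC (", paste(curve$qc_notes, collapse = "; "),
         "); pass override_qc = TRUE to quantify anyway")
  one <- function(q) {
    copies_rxn <- 10^((q - curve$intercept) / curve$slope)
    copies_g <- copies_rxn * scale
    structure(list(copies_per_g = copies_g,
                   below_loq = copies_g < loq,
                   assay = assay,
                   qc_overridden = !curve$qc_pass), class = "copy_estimate")
  }
  if (per_replicate) lapply(cq, one) else one(mean(cq))
}

#' Read a qPCR table and quantify every unknown
#'
#' Expects CSV columns `assay, role, log10_copies, cq, scale_factor` with
#' `role` in `standard`/`unknown` (`log10_copies` blank for unknowns). One
#' standard curve is fitted per assay; unknowns of that assay are averaged
#' (mean Cq) and quantified.
#'
#' @param path CSV path.
#' @param loq Limit of quantification, copies g^-1.
#' @param ... Passed to [fit_standard_curve()].
#' @return List per assay: `curve` (a `standard_curve`) and `estimate`
#'   (a `copy_estimate`, or `NULL` when the assay has no unknowns).
#' @export
quantify_qpcr_table <- function(path, loq = 1e2, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("assay", "role", "log10_copies", "cq", "scale_factor")
  if (!all(needed %in% names(df)))
    stop("qPCR table needs columns: ", paste(needed, collapse = ", "))
  out <- list()
  for (a in unique(df$assay)) {
    sub <- df[df$assay == a, ]
    std <- sub[sub$role == "standard", ]
    unk <- sub[sub$role == "unknown", ]
    curve <- fit_standard_curve(std$log10_copies, std$cq, ...)
    est <- NULL
    if (nrow(unk)) {
      scale <- unique(unk$scale_factor)
      if (length(scale) != 1)
        stop(sprintf("assay '%s': unknowns carry differing scale_factor", a))
      est <- quantify_sample(unk$cq, curve, scale = scale, loq = loq, assay = a)
    }
    out[[a]] <- list(curve = curve, estimate = est)
  }
  out
}
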