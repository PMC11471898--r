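## Per-group N2O metrics. Yields are dimensionally ng N2O-N per ug
## NH4+-N, i.e. parts per thousand of the oxidized nitrogen re-emitted as
## N2O-N. Cell-specific rates normalise the emission rate by amoA copies
## as a per-cell proxy, on a nitrogen basis: mass of N2O-N divided by the
## atomic mass of N (14.007), so each mol of N2O counts its two N atoms.

#' N2O yield of an ammonia-oxidizer group
#'
#' Yield = cumulative group N2O-N (ng g^-1) divided by NH4+-N oxidized
#' (ug g^-1) over the same period; ng/ug is reported as permil.
#'
#' @param group_n2o Cumulative group N2O emission, ng N2O-N g^-1.
#' @param rate Group nitrification rate, ug N g^-1 d^-1 (>= 0).
#' @param duration_days Incubation length in days (> 0).
#' @return List: `yield_permil` and `undefined` (TRUE when nothing was
#'   oxidized but N2O was produced — the yield is flagged, not infinite).
#' @examples
#' n2o_yield(0.179 * 2.52, 0.49, 3)$yield_permil  # ~0.31 permil
#' @export
n2o_yield <- function(group_n2o, rate, duration_days) {
  if (rate < 0) stop("rate must be >= 0")
  if (duration_days <= 0) stop("duration must be > 0")
  if (group_n2o < 0) stop("group N2O must be >= 0")
  oxidized <- rate * duration_days  # ug NH4+-N g^-1
  if (oxidized == 0) {
    if (group_n2o > 0)
      return(list(yield_permil = NA_real_, undefined = TRUE))
    return(list(yield_permil = 0, undefined = FALSE))
  }
  list(yield_permil = group_n2o / oxidized, undefined = FALSE)
}

#' Cell-specific N2O production rate
#'
#' Emission rate per marker-gene copy, on a nitrogen basis: the cumulative
#' group emission over the incubation is converted to an hourly rate,
#' divided by the atomic mass of nitrogen (14.007 g mol^-1) to give moles
#' of N2O-N, and divided by amoA copies per gram as a cell-number proxy.
#' Reported in amol (1e-18 mol) per copy per hour.
#'
#' @param group_n2o Cumulative group N2O emission, ng N2O-N g^-1.
#' @param duration_h Incubation length in hours (> 0).
#' @param copies amoA copies g^-1 (> 0); pass a `copy_estimate` or a bare
#'   number.
#' @param strict_loq If `TRUE` and `copies` is a below-LOQ
#'   `copy_estimate`, return `NA` with a flag instead of a value.
#' @return List: `rate_amol` (amol N2O-N copy^-1 h^-1), `below_loq` flag.
#' @examples
#' cell_specific_rate(0.179 * 2.52, 72, 1.5e7)$rate_amol  # ~0.03
#' @export
cell_specific_rate <- function(group_n2o, duration_h, copies,
                               strict_loq = FALSE) {
  below_loq <- FALSE
  if (inherits(copies, "copy_estimate")) {
    below_loq <- isTRUE(copies$below_loq)
    copies <- copies$copies_per_g
  }
  if (!is.finite(copies) || copies <= 0) stop("copies must be > 0")
  if (duration_h <= 0) stop("duration must be > 0")
  if (group_n2o < 0) stop("group N2O must be >= 0")
  if (below_loq && strict_loq)
    return(list(rate_amol = NA_real_, below_loq = TRUE))
  ## ng g^-1 -> g g^-1 (1e-9), / M_N -> mol N, -> amol (1e18): net 1e9
  rate_amol <- group_n2o / duration_h / M_NITROGEN / copies * 1e9
  list(rate_amol = rate_amol, below_loq = below_loq)
}

#' Per-group yield and cell-specific metrics from a partition
#'
#' Computes [n2o_yield()] and [cell_specific_rate()] for every resolvable
#' ammonia-oxidizer group of a `partition_result`. The group emission may
#' come directly from the partition or, equivalently, as contribution_pct
#' x total N2O — the two paths agree by construction.
#'
#' @param part A `partition_result`.
#' @param copies Named list/vector of amoA copies g^-1 (or
#'   `copy_estimate`s) for `AOA`, `AOB`, `CMX`.
#' @param duration_h Incubation length, hours.
#' @param strict_loq Propagated to [cell_specific_rate()].
#' @return Data frame over AO groups: `group`, `yield_permil`,
#'   `yield_undefined`, `cell_specific_amol`, `below_loq`, plus echoed
#'   inputs (`n2o_emission`, `nitrification_rate`, `copies`).
#' @export
group_metrics <- function(part, copies, duration_h, strict_loq = FALSE) {
  a <- part$attributions
  a <- a[a$group %in% AO_GROUPS, ]
  duration_days <- duration_h / 24
  rows <- lapply(seq_len(nrow(a)), function(i) {
    g <- a$group[i]
    if (is.na(a$n2o_emission[i]) || is.na(a$nitrification_rate[i]))
      return(data.frame(group = g, yield_permil = NA_real_,
                        yield_undefined = NA, cell_specific_amol = NA_real_,
                        below_loq = NA, n2o_emission = NA_real_,
                        nitrification_rate = NA_real_, copies = NA_real_))
    y <- n2o_yield(a$n2o_emission[i], a$nitrification_rate[i], duration_days)
    cp <- copies[[g]]
    cs <- if (is.null(cp)) list(rate_amol = NA_real_, below_loq = NA) else
      cell_specific_rate(a$n2o_emission[i], duration_h, cp, strict_loq)
    data.frame(group = g, yield_permil = y$yield_permil,
               yield_undefined = y$undefined,
               cell_specific_amol = cs$rate_amol, below_loq = cs$below_loq,
               n2o_emission = a$n2o_emission[i],
               nitrification_rate = a$nitrification_rate[i],
               copies = if (inherits(cp, "copy_estimate")) cp$copies_per_g
                        else if (is.null(cp)) NA_real_ else cp)
  })
  do.call(rbind, rows)
}
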