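## Headspace N2O accounting. Serum bottles are destructively sampled, so
## each timepoint's bottle carries the full mixing ratio accumulated since
## t = 0; cumulative emission is baseline-subtracted mass, never a summed
## flux, and no leakage correction applies.

#' Convert a headspace N2O mixing ratio to mass per gram of sample
#'
#' Ideal-gas conversion: the headspace holds `n = P V / (R T)` moles of
#' gas, a fraction `x * 1e-9` of which is N2O at mixing ratio `x` ppb.
#' N2O-N mass counts both nitrogen atoms (2 x 14.007 g per mol N2O) and is
#' normalised by fresh sample mass.
#'
#' @param mixing_ratio_ppb N2O mixing ratio(s), ppb v/v; vectorised.
#' @param design A [microcosm_design()] supplying headspace volume
#'   (`bottle_volume - sample_volume`, mL), temperature (K), pressure (kPa)
#'   and sample mass (g).
#' @return N2O-N mass in ng per g of sample; exactly linear in the mixing
#'   ratio.
#' @examples
#' d <- microcosm_design()  # 48 mL headspace, 298.15 K, 101.325 kPa, 2 g
#' headspace_n2o_mass(100, d)  # ~2.75 ng N2O-N g^-1
#' @export
headspace_n2o_mass <- function(mixing_ratio_ppb, design) {
  v_headspace_ml <- design$bottle_volume - design$sample_volume
  if (v_headspace_ml <= 0)
    stop("non-positive headspace volume: bottle_volume must exceed sample_volume")
  if (design$temperature <= 0) stop("temperature must be > 0 K")
  if (any(mixing_ratio_ppb < 0)) stop("mixing ratio must be >= 0 ppb")
  ## moles of headspace gas: P [Pa] * V [m^3] / (R T)
  n_total <- design$pressure * 1e3 * v_headspace_ml * 1e-6 /
    (GAS_CONSTANT * design$temperature)
  n_n2o <- n_total * mixing_ratio_ppb * 1e-9           # mol N2O
  mass_n_g <- n_n2o * 2 * M_NITROGEN                   # g N2O-N
  mass_n_g * 1e9 / design$sample_mass                  # ng N2O-N g^-1
}

#' Invert the headspace conversion (mass back to mixing ratio)
#'
#' @param mass_ng_per_g N2O-N mass in ng g^-1.
#' @inheritParams headspace_n2o_mass
#' @return Mixing ratio in ppb v/v. `n2o_ppb_from_mass(headspace_n2o_mass(x, d), d)`
#'   returns `x` to machine precision.
#' @export
n2o_ppb_from_mass <- function(mass_ng_per_g, design) {
  unit <- headspace_n2o_mass(1, design)
  mass_ng_per_g / unit
}

#' Cumulative N2O emission from a headspace time series
#'
#' Converts each reading to mass, subtracts the t = 0 baseline and reports
#' the per-timepoint trace plus the cumulative emission at the final
#' timepoint. Replicate readings at the same timepoint are averaged before
#' subtraction.
#'
#' @param series Data frame with columns `time_h` and `mixing_ratio_ppb`
#'   (replicates may repeat timepoints).
#' @inheritParams headspace_n2o_mass
#' @return List with `trace` (data frame: `time_h`, `mass_ng_g`, the
#'   baseline-subtracted mass) and `cumulative` (ng N2O-N g^-1 at the final
#'   timepoint).
#' @export
cumulative_emission <- function(series, design) {
  if (!all(c("time_h", "mixing_ratio_ppb") %in% names(series)))
    stop("series needs columns time_h and mixing_ratio_ppb")
  if (!any(series$time_h == 0))
    stop("series has no t = 0 reading; baseline subtraction impossible")
  mass <- headspace_n2o_mass(series$mixing_ratio_ppb, design)
  mean_mass <- tapply(mass, series$time_h, mean)
  times <- as.numeric(names(mean_mass))
  o <- order(times)
  times <- times[o]; mean_mass <- as.numeric(mean_mass)[o]
  baseline <- mean_mass[times == 0]
  trace <- data.frame(time_h = times, mass_ng_g = mean_mass - baseline)
  list(trace = trace, cumulative = trace$mass_ng_g[which.max(trace$time_h)])
}

#' Append derived N2O mass records to a measurement table
#'
#' Every `N2O_ppb` record is converted with [headspace_n2o_mass()] and
#' appended as an `N2O_mass` record with the same keys, so downstream
#' kinetics can consume mass series regardless of how N2O was supplied.
#' Tables already containing `N2O_mass` records are returned unchanged.
#'
#' @param table A `measurement_table`.
#' @param design A [microcosm_design()].
#' @return A `measurement_table` including `N2O_mass` records.
#' @export
add_n2o_mass <- function(table, design) {
  if (any(table$analyte == "N2O_mass")) return(table)
  ppb <- table[table$analyte == "N2O_ppb", , drop = FALSE]
  if (nrow(ppb) == 0) return(table)
  derived <- ppb
  derived$analyte <- "N2O_mass"
  derived$value <- headspace_n2o_mass(ppb$value, design)
  measurement_table(rbind(as.data.frame(table), as.data.frame(derived)), design)
}
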