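## Synthetic microcosm, qPCR and abundance generators with known ground
## truth, so every pipeline stage can be validated end-to-end. Substrate
## kinetics are zero-order (linear depletion): reported nitrification
## rates are constant ug N g^-1 d^-1 over the 3-day incubation, implying
## ammonium is not yet limiting at these levels. Measurement noise is
## additive Gaussian per destructively sampled bottle.

#' Ground truth for a simulated microcosm experiment
#'
#' The default preset mirrors a mature coastal-plastisphere community in
#' which comammox Nitrospira dominate ammonia oxidation: group rates
#' (AOA 0.22, AOB 0.04, CMX 0.49 ug N g^-1 d^-1) and group N2O yields
#' scaled so the control microcosm emits 2.52 ng N2O-N g^-1 over 3 days
#' with 55.9% of it from non-nitrification processes.
#'
#' @param group_rates Named vector, ug N g^-1 d^-1 for AOA/AOB/CMX.
#' @param group_yields Named vector, permil (ng N2O-N per ug NH4+-N).
#' @param non_ao_n2o_rate Non-nitrification N2O production,
#'   ng N2O-N g^-1 d^-1.
#' @param inhibitor_efficacy Optional matrix (treatment x group) in
#'   `[0,1]`; `NULL` means every declared inhibition is complete
#'   (efficacy 1) and every non-declared pair is untouched (efficacy 0).
#' @param initial_nh4 Extractable NH4+-N at t = 0, ug N g^-1.
#' @param noise_sd_nh4,noise_sd_n2o Gaussian measurement SDs
#'   (ug N g^-1; ng N2O-N g^-1).
#' @param ambient_n2o_ppb Headspace N2O mixing ratio at t = 0 (ambient
#'   air), ppb.
#' @param replicates Bottles per treatment-timepoint.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(group_rates = c(AOA = 0.22, AOB = 0.04, CMX = 0.49),
                             group_yields = c(AOA = 0.214 * 2.52 / (0.22 * 3),
                                              AOB = 0.048 * 2.52 / (0.04 * 3),
                                              CMX = 0.179 * 2.52 / (0.49 * 3)),
                             non_ao_n2o_rate = 0.559 * 2.52 / 3,
                             inhibitor_efficacy = NULL,
                             initial_nh4 = 10,
                             noise_sd_nh4 = 0,
                             noise_sd_n2o = 0,
                             ambient_n2o_ppb = 330,
                             replicates = 3,
                             seed = 1) {
  stopifnot(all(group_rates >= 0), all(group_yields >= 0),
            non_ao_n2o_rate >= 0, initial_nh4 > 0,
            noise_sd_nh4 >= 0, noise_sd_n2o >= 0, replicates >= 1)
  structure(list(
    group_rates = group_rates[AO_GROUPS],
    group_yields = group_yields[AO_GROUPS],
    non_ao_n2o_rate = non_ao_n2o_rate,
    inhibitor_efficacy = inhibitor_efficacy,
    initial_nh4 = initial_nh4,
    noise_sd_nh4 = noise_sd_nh4,
    noise_sd_n2o = noise_sd_n2o,
    ambient_n2o_ppb = ambient_n2o_ppb,
    replicates = replicates,
    seed = seed
  ), class = "simulation_truth")
}

## Efficacy of treatment trt on group g: user matrix wins, else 1 iff the
## design declares g inhibited in trt.
.efficacy <- function(truth, scheme, trt, g) {
  if (!is.null(truth$inhibitor_efficacy)) {
    m <- truth$inhibitor_efficacy
    if (trt %in% rownames(m) && g %in% colnames(m)) return(m[trt, g])
  }
  as.numeric(g %in% scheme[[trt]])
}

#' Simulate a nested-inhibitor microcosm incubation
#'
#' For each treatment, replicate bottle and timepoint, ammonium declines
#' linearly at the summed residual (uninhibited) group rate and N2O
#' accumulates from the group yields plus the non-nitrification
#' background; Gaussian noise is added per reading and N2O is emitted as
#' a headspace mixing ratio on top of the ambient baseline, exactly as a
#' GC would see it.
#'
#' @param truth A [simulation_truth()].
#' @param design A valid [microcosm_design()].
#' @return A `measurement_table` with `NH4_N` and `N2O_ppb` records; the
#'   truth is attached as `attr(, "truth")`. A warning is raised (and
#'   `attr(, "nh4_truncated")` set) if ammonium would go negative before
#'   the final timepoint.
#' @export
simulate_microcosm <- function(truth, design) {
  v <- validate_design(design)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  scheme <- design$inhibitor_scheme
  set.seed(truth$seed)
  rows <- list()
  truncated <- FALSE
  for (trt in names(scheme)) {
    resid_rate <- sum(vapply(AO_GROUPS, function(g)
      truth$group_rates[[g]] * (1 - .efficacy(truth, scheme, trt, g)),
      numeric(1)))
    n2o_rate <- sum(vapply(AO_GROUPS, function(g)
      truth$group_rates[[g]] * (1 - .efficacy(truth, scheme, trt, g)) *
        truth$group_yields[[g]], numeric(1))) + truth$non_ao_n2o_rate
    for (rep in seq_len(truth$replicates)) {
      for (t in design$timepoints) {
        nh4_true <- truth$initial_nh4 - resid_rate * t / 24
        if (nh4_true < 0) { truncated <- TRUE; nh4_true <- 0 }
        nh4 <- nh4_true + stats::rnorm(1, 0, truth$noise_sd_nh4)
        mass_true <- n2o_rate * t / 24
        mass <- mass_true + stats::rnorm(1, 0, truth$noise_sd_n2o)
        ppb <- truth$ambient_n2o_ppb + n2o_ppb_from_mass(mass, design)
        rows[[length(rows) + 1]] <- data.frame(
          treatment = trt, replicate = rep, time_h = t,
          analyte = c("NH4_N", "N2O_ppb"),
          value = pmax(c(nh4, ppb), 0))
      }
    }
  }
  if (truncated)
    warning("NH4+ pool exhausted before the final timepoint; series truncated at 0")
  tab <- measurement_table(do.call(rbind, rows), design)
  attr(tab, "truth") <- truth
  attr(tab, "nh4_truncated") <- truncated
  tab
}

#' Simulate a qPCR plate for one assay
#'
#' Standards follow an exact log-linear Cq response over a 10-fold
#' dilution series; the unknown's Cq is generated from the true copy
#' number through the same curve. Gaussian Cq noise, deterministic under
#' the seed.
#'
#' @param true_copies_per_g True abundance, copies g^-1 (> 0).
#' @param slope,intercept Curve parameters (Cq per log10 copies; Cq at 1
#'   copy per reaction).
#' @param scale Reaction-to-per-gram factor (see [quantify_sample()]).
#' @param standard_log10 log10 copies of the dilution series.
#' @param n_unknown_reps Technical replicates of the unknown.
#' @param cq_noise_sd Gaussian SD on every Cq.
#' @param seed Integer seed.
#' @param assay Assay label.
#' @return Data frame in the qPCR table schema
#'   (`assay, role, log10_copies, cq, scale_factor`).
#' @export
simulate_qpcr <- function(true_copies_per_g, slope = -1 / log10(2),
                          intercept = 38, scale = 1,
                          standard_log10 = 7:2, n_unknown_reps = 3,
                          cq_noise_sd = 0, seed = 1, assay = "CMX") {
  stopifnot(true_copies_per_g > 0, scale > 0, slope < 0)
  set.seed(seed)
  cq_std <- intercept + slope * standard_log10 +
    stats::rnorm(length(standard_log10), 0, cq_noise_sd)
  log10_rxn <- log10(true_copies_per_g / scale)
  cq_unk <- intercept + slope * log10_rxn +
    stats::rnorm(n_unknown_reps, 0, cq_noise_sd)
  rbind(
    data.frame(assay = assay, role = "standard",
               log10_copies = standard_log10, cq = cq_std,
               scale_factor = scale),
    data.frame(assay = assay, role = "unknown",
               log10_copies = NA_real_, cq = cq_unk, scale_factor = scale)
  )
}

#' Simulate abundance time series with covariate trends
#'
#' Generates monotone-in-expectation abundance series (linear by default,
#' so a noise-free series correlates perfectly with a linear covariate;
#' geometric optionally) with multiplicative log-normal noise, plus
#' linearly trending covariates within configured ranges (e.g. EPS
#' polysaccharide and protein rising as the biofilm matures, seawater
#' NH4+ declining within 0.15-0.58 mg L^-1).
#'
#' @param fold_over_period Target last/first ratio at zero noise.
#' @param months Sampling months (strictly increasing).
#' @param initial Abundance at the first month (> 0), e.g. percent.
#' @param shape `"linear"` or `"geometric"` interpolation.
#' @param covariate_trends Named list: covariate -> `c(from, to)` endpoint
#'   values, interpolated linearly over the months.
#' @param noise_sd SD of multiplicative log-normal noise on abundances.
#' @param seed Integer seed.
#' @param entity Series label.
#' @return List: `abundance` (data frame `entity, month, value`) and
#'   `covariates` (data frame `month` + one column per covariate).
#' @export
simulate_abundance_series <- function(fold_over_period, months = c(3, 6, 12, 15, 21, 27, 39),
                                      initial = 0.02, shape = c("linear", "geometric"),
                                      covariate_trends = list(PS = c(2, 20),
                                                              PN = c(1, 10),
                                                              NH4 = c(0.58, 0.15)),
                                      noise_sd = 0, seed = 1, entity = "taxon") {
  shape <- match.arg(shape)
  stopifnot(initial > 0, fold_over_period > 0, all(diff(months) > 0))
  set.seed(seed)
  frac <- (months - months[1]) / (months[length(months)] - months[1])
  base <- switch(shape,
                 linear = initial * (1 + (fold_over_period - 1) * frac),
                 geometric = initial * fold_over_period^frac)
  values <- base * exp(stats::rnorm(length(base), 0, noise_sd))
  covs <- data.frame(month = months)
  for (nm in names(covariate_trends)) {
    ft <- covariate_trends[[nm]]
    covs[[nm]] <- ft[1] + (ft[2] - ft[1]) * frac
  }
  list(abundance = data.frame(entity = entity, month = months, value = values),
       covariates = covs)
}
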