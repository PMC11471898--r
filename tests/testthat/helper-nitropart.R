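# Shared fixtures built in code.

# A treatment_summary from bare numbers (bypasses time-series fitting).
make_summary <- function(treatment, rate, n2o, rate_se = 0, n2o_se = 0) {
  structure(list(treatment = treatment,
                 nitrification_rate = max(rate, 0), rate_raw = rate,
                 rate_se = rate_se, n2o_cumulative = n2o, n2o_se = n2o_se,
                 n_replicates = 3, low_support = FALSE),
            class = "treatment_summary")
}

# Summaries for the canonical four-treatment chain from per-treatment
# rates and cumulative N2O emissions (in scheme order).
chain_summaries <- function(rates, n2o) {
  trts <- c("control", "octyne", "dmpp", "acetylene")
  out <- Map(make_summary, trts, rates, n2o)
  names(out) <- trts
  out
}

default_scheme <- function() microcosm_design()$inhibitor_scheme

# Treatment-level emissions that reproduce given group contribution
# percentages of a control total (chain order: AOB, CMX, AOA differences).
emissions_from_contributions <- function(total, pct_aoa, pct_aob, pct_cmx) {
  octyne <- total - pct_aob / 100 * total
  dmpp <- octyne - pct_cmx / 100 * total
  acetylene <- dmpp - pct_aoa / 100 * total
  c(control = total, octyne = octyne, dmpp = dmpp, acetylene = acetylene)
}

# Noise-free plastisphere-like measurement table with derived N2O mass.
zero_noise_table <- function(seed = 1) {
  d <- microcosm_design()
  tab <- simulate_microcosm(simulation_truth(seed = seed), d)
  add_n2o_mass(tab, d)
}
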