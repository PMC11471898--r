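test_that("the generator is byte-deterministic under its seed", {
  d <- microcosm_design()
  tr <- simulation_truth(noise_sd_nh4 = 0.5, noise_sd_n2o = 0.1, seed = 99)
  a <- simulate_microcosm(tr, d)
  b <- simulate_microcosm(tr, d)
  expect_identical(as.data.frame(a), as.data.frame(b))
  tr2 <- simulation_truth(noise_sd_nh4 = 0.5, noise_sd_n2o = 0.1, seed = 100)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_microcosm(tr2, d))))
})

test_that("control ammonium declines at exactly the summed group rate", {
  d <- microcosm_design()
  tr <- simulation_truth(group_rates = c(AOA = 0.40, AOB = 0.24, CMX = 0.30))
  tab <- simulate_microcosm(tr, d)
  ctl <- tab[tab$treatment == "control" & tab$analyte == "NH4_N", ]
  f <- fit_linear_rate(ctl$time_h, ctl$value)
  expect_equal(f$slope_per_day, -0.94, tolerance = 1e-12)
})

test_that("ammonium exhaustion triggers truncation warning and flag", {
  d <- microcosm_design()
  tr <- simulation_truth(group_rates = c(AOA = 4, AOB = 0, CMX = 0),
                         initial_nh4 = 2)
  expect_warning(tab <- simulate_microcosm(tr, d), "exhausted")
  expect_true(attr(tab, "nh4_truncated"))
  expect_true(all(tab$value >= 0))
})

test_that("the full pipeline recovers configured truth exactly at zero noise", {
  d <- microcosm_design()
  tr <- simulation_truth()
  tab <- add_n2o_mass(simulate_microcosm(tr, d), d)
  p <- partition(summarize_all_treatments(tab, d), d$inhibitor_scheme)
  a <- p$attributions
  for (g in c("AOA", "AOB", "CMX")) {
    rate_true <- tr$group_rates[[g]]
    n2o_true <- tr$group_rates[[g]] * tr$group_yields[[g]] * 3
    expect_equal(a$nitrification_rate[a$group == g], rate_true,
                 tolerance = 1e-9)
    expect_equal(a$n2o_emission[a$group == g], n2o_true, tolerance = 1e-9)
    expect_equal(a$contribution_pct[a$group == g], 100 * n2o_true / 2.52,
                 tolerance = 1e-9)
  }
  expect_equal(p$total_n2o, 2.52, tolerance = 1e-9)
  expect_equal(p$non_ao_pct, 55.9, tolerance = 1e-9)
  m <- group_metrics(p, list(AOA = 1.6e6, AOB = 6.1e4, CMX = 1.5e7), 72)
  expect_equal(m$yield_permil, unname(tr$group_yields[m$group]),
               tolerance = 1e-9)
})

test_that("halving octyne efficacy on AOB moves rate from AOB to CMX equally", {
  d <- microcosm_design()
  eff <- matrix(1, nrow = 4, ncol = 3,
                dimnames = list(names(d$inhibitor_scheme), c("AOA", "AOB", "CMX")))
  eff["control", ] <- 0
  eff["octyne", c("AOA", "CMX")] <- 0
  eff["dmpp", "AOA"] <- 0
  full <- simulation_truth()
  weak <- simulation_truth(inhibitor_efficacy = {
    m <- eff; m["octyne", "AOB"] <- 0.5; m
  })
  pf <- partition(summarize_all_treatments(
    add_n2o_mass(simulate_microcosm(full, d), d), d), d$inhibitor_scheme)
  pw <- partition(summarize_all_treatments(
    add_n2o_mass(simulate_microcosm(weak, d), d), d), d$inhibitor_scheme)
  af <- pf$attributions; aw <- pw$attributions
  d_aob <- aw$nitrification_rate[aw$group == "AOB"] -
    af$nitrification_rate[af$group == "AOB"]
  d_cmx <- aw$nitrification_rate[aw$group == "CMX"] -
    af$nitrification_rate[af$group == "CMX"]
  expect_lt(d_aob, 0)
  expect_equal(d_aob, -d_cmx, tolerance = 1e-9)
  # the control - acetylene span is conserved
  expect_equal(sum(af$nitrification_rate[af$group != "non_AO"]),
               sum(aw$nitrification_rate[aw$group != "non_AO"]),
               tolerance = 1e-9)
})

test_that("simulated abundance hits its fold target and covariate signs", {
  sim <- simulate_abundance_series(35, noise_sd = 0)
  v <- sim$abundance$value
  expect_equal(fold_change(v[1], v[length(v)])$fold, 35)
  # rising abundance against declining NH4: negative r in nearly all seeds
  signs <- vapply(1:100, function(s) {
    sm <- simulate_abundance_series(10, noise_sd = 0.15, seed = s)
    pearson_correlation(sm$abundance$value, sm$covariates$NH4)$r < 0
  }, logical(1))
  expect_gte(sum(signs), 95)
})
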