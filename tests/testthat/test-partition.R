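# Subtraction oracle for the canonical chain:
#   AOB = control - octyne, CMX = octyne - dmpp, AOA = dmpp - acetylene,
#   non-AO = acetylene.

test_that("nested differencing attributes rates and emissions per group", {
  s <- chain_summaries(rates = c(1.04, 0.80, 0.50, 0.10),
                       n2o = c(2.52, 2.40, 1.90, 1.41))
  p <- partition(s, default_scheme())
  a <- p$attributions
  expect_equal(a$nitrification_rate[a$group == "AOB"], 0.24)
  expect_equal(a$nitrification_rate[a$group == "CMX"], 0.30)
  expect_equal(a$nitrification_rate[a$group == "AOA"], 0.40)
  expect_equal(a$n2o_emission[a$group == "non_AO"], 1.41)
  expect_true(p$fully_resolved)

  # exact identity: pre-clamp group emissions + non-AO = control total
  expect_equal(sum(a$n2o_raw), p$total_n2o, tolerance = 1e-12)
  expect_equal(sum(a$contribution_pct), 100, tolerance = 1e-9)
  expect_equal(p$ao_attributed_pct + p$non_ao_pct, 100)
})

test_that("identical treatments give zero group activity, 100% non-AO", {
  s <- chain_summaries(rates = rep(0.5, 4), n2o = rep(1.2, 4))
  p <- partition(s, default_scheme())
  a <- p$attributions
  expect_equal(a$nitrification_rate[a$group != "non_AO"], rep(0, 3))
  expect_equal(a$n2o_emission[a$group != "non_AO"], rep(0, 3))
  expect_equal(p$non_ao_pct, 100)
})

test_that("SEs combine in quadrature across the differenced treatments", {
  s <- chain_summaries(rates = c(1, 0.7, 0.4, 0.1), n2o = c(2, 1.8, 1.5, 1))
  s$control$rate_se <- 0.03; s$octyne$rate_se <- 0.04
  p <- partition(s, default_scheme())
  a <- p$attributions
  expect_equal(a$rate_se[a$group == "AOB"], sqrt(0.03^2 + 0.04^2))
})

test_that("negative differences are clamped with the raw value retained", {
  # sediment-like: DMPP emission above octyne's (inhibitor noise) -> CMX < 0
  s <- chain_summaries(rates = c(0.9, 0.55, 0.60, 0.05),
                       n2o = c(1.81, 1.50, 1.52, 0.93))
  p <- partition(s, default_scheme())
  a <- p$attributions
  expect_equal(a$n2o_emission[a$group == "CMX"], 0)
  expect_lt(a$n2o_raw[a$group == "CMX"], 0)
  expect_true("CMX" %in% p$clamped_groups)
  # no renormalisation: the clamp leaves a visible residual
  expect_equal(p$residual_after_clamp,
               p$total_n2o - sum(a$n2o_emission), tolerance = 1e-12)
  expect_lt(p$residual_after_clamp, 0)
})

test_that("shifting activity between octyne and DMPP steps trades AOB for CMX", {
  base <- chain_summaries(rates = c(1.0, 0.7, 0.4, 0.0), n2o = c(2, 1.6, 1.2, 0.8))
  up <- chain_summaries(rates = c(1.0, 0.8, 0.4, 0.0), n2o = c(2, 1.7, 1.2, 0.8))
  pb <- partition(base, default_scheme())$attributions
  pu <- partition(up, default_scheme())$attributions
  d_aob <- pu$nitrification_rate[pu$group == "AOB"] -
    pb$nitrification_rate[pb$group == "AOB"]
  d_cmx <- pu$nitrification_rate[pu$group == "CMX"] -
    pb$nitrification_rate[pb$group == "CMX"]
  expect_equal(d_aob, -0.1)
  expect_equal(d_cmx, +0.1)  # conserved control - acetylene span
})

test_that("schemes with confounded or missing steps degrade gracefully", {
  scheme2 <- list(control = character(0), acetylene = c("AOA", "AOB", "CMX"))
  s2 <- list(control = make_summary("control", 1, 2),
             acetylene = make_summary("acetylene", 0.1, 0.9))
  p2 <- partition(s2, scheme2)
  expect_false(p2$fully_resolved)
  expect_true(all(is.na(p2$attributions$n2o_emission[p2$attributions$group != "non_AO"])))
  expect_equal(p2$attributions$n2o_emission[p2$attributions$group == "non_AO"], 0.9)

  expect_error(partition(s2["control"], scheme2), "missing treatment")
  bad <- list(control = character(0), octyne = "AOB", dmpp = "CMX")
  expect_error(partition(chain_summaries(1:4 / 4, 4:1 / 2)[1:3], bad), "nested")
})

test_that("bootstrap intervals are seed-deterministic and collapse at zero noise", {
  d <- microcosm_design()
  tab0 <- zero_noise_table()
  p0 <- propagate_uncertainty(tab0, d, n_boot = 50, seed = 42)
  expect_equal(p0$intervals$rate_lo, p0$intervals$rate_hi, tolerance = 1e-10)

  tabn <- add_n2o_mass(simulate_microcosm(
    simulation_truth(noise_sd_nh4 = 0.5, noise_sd_n2o = 0.1, seed = 8), d), d)
  a <- propagate_uncertainty(tabn, d, n_boot = 100, seed = 7)
  b <- propagate_uncertainty(tabn, d, n_boot = 100, seed = 7)
  expect_identical(a$intervals, b$intervals)
  c2 <- propagate_uncertainty(tabn, d, n_boot = 100, seed = 8)
  expect_false(identical(a$intervals$rate_lo, c2$intervals$rate_lo))
  expect_error(propagate_uncertainty(tabn, d, n_boot = 0), "n_boot")
})
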