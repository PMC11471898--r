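# Closed-form regression oracle for the worked series:
# t = (0,24,48,72) h, NH4 = (10, 9, 8.2, 6.8):
#   Sxy = -124.8, Sxx = 2880 -> slope = -0.0433... h^-1 = -1.04 d^-1

test_that("OLS rate matches hand-computed and brute-force oracles", {
  f <- fit_linear_rate(c(0, 24, 48, 72), c(10, 9, 8.2, 6.8))
  expect_equal(f$slope_per_day, -1.04, tolerance = 1e-12)

  # constant series
  expect_equal(fit_linear_rate(c(0, 24, 48), c(5, 5, 5))$slope_per_day, 0)
  # exact two-point line, saturated fit: SE is 0
  f2 <- fit_linear_rate(c(0, 72), c(10, 7))
  expect_equal(f2$slope_per_day, -1)
  expect_equal(f2$se_per_day, 0)
  expect_error(fit_linear_rate(c(24, 24), c(1, 2)), "distinct")

  # independent normal-equation oracle on random small inputs
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    t <- sort(runif(n, 0, 96))
    y <- 10 - 0.05 * t + rnorm(n, 0, 0.5)
    oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_equal(fit_linear_rate(t, y)$slope_per_hour, oracle, tolerance = 1e-10)
  }
})

test_that("rate estimate is shift-invariant and scale-equivariant", {
  t <- c(0, 24, 48, 72); y <- c(10, 9.1, 8.0, 7.2)
  base <- fit_linear_rate(t, y)$slope_per_day
  expect_equal(fit_linear_rate(t, y + 100)$slope_per_day, base)
  expect_equal(fit_linear_rate(t, y * 3)$slope_per_day, base * 3)
})

test_that("treatment summaries recover configured truth at zero noise", {
  d <- microcosm_design()
  tr <- simulation_truth()  # AOA 0.22 + AOB 0.04 + CMX 0.49 = 0.75 total
  tab <- add_n2o_mass(simulate_microcosm(tr, d), d)
  s <- summarize_treatment(tab, "control")
  expect_equal(s$nitrification_rate, 0.75, tolerance = 1e-12)
  expect_equal(s$n2o_cumulative, 2.52, tolerance = 1e-12)
  expect_equal(s$n_replicates, 3)

  # acetylene silences everything: only the non-AO background remains
  s4 <- summarize_treatment(tab, "acetylene")
  expect_equal(s4$nitrification_rate, 0, tolerance = 1e-12)
  expect_equal(s4$n2o_cumulative, 0.559 * 2.52, tolerance = 1e-12)
})

test_that("summaries are invariant to permuting replicate labels", {
  d <- microcosm_design()
  tab <- add_n2o_mass(simulate_microcosm(
    simulation_truth(noise_sd_nh4 = 0.4, noise_sd_n2o = 0.05, seed = 2), d), d)
  perm <- as.data.frame(tab)
  perm$replicate <- c(2L, 3L, 1L)[perm$replicate]
  perm <- measurement_table(perm, d)
  a <- summarize_treatment(tab, "control")
  b <- summarize_treatment(perm, "control")
  expect_equal(a$nitrification_rate, b$nitrification_rate)
  expect_equal(a$n2o_cumulative, b$n2o_cumulative)
  expect_equal(a$rate_se, b$rate_se)
})

test_that("single-replicate two-timepoint data is flagged low-support", {
  d <- microcosm_design(timepoints = c(0, 72))
  tr <- simulation_truth(replicates = 1)
  tab <- add_n2o_mass(simulate_microcosm(tr, d), d)
  s <- summarize_treatment(tab, "control")
  expect_true(s$low_support)
  expect_equal(s$rate_se, 0)
  expect_equal(s$n2o_se, 0)
})

test_that("per-replicate and pooled fits agree on balanced noise-free data", {
  d <- microcosm_design()
  tab <- add_n2o_mass(simulate_microcosm(simulation_truth(), d), d)
  pooled <- summarize_treatment(tab, "control")
  per_rep <- summarize_treatment(tab, "control", per_replicate = TRUE)
  expect_equal(pooled$nitrification_rate, per_rep$nitrification_rate,
               tolerance = 1e-12)
})

test_that("one-way ANOVA matches the hand-computed F and its invariances", {
  # SSB = 13.5, SSW = 4, df 1/4 -> F = 13.5
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$f, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  # identical group means: F = 0, p = 1
  b <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(b$f, 0)
  expect_equal(b$p, 1)
  # shift invariance
  sh <- anova_oneway(list(c(1, 2, 3) + 7, c(4, 5, 6) + 7))
  expect_equal(sh$f, a$f)
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "identical")
  expect_error(anova_oneway(list(1, c(2, 3))), "n >= 2")
})

test_that("Fisher's LSD uses pooled variance and unadjusted p values", {
  same <- fisher_lsd(list(a = c(1, 2, 3), b = c(1.1, 2.1, 2.9),
                          c = c(0.9, 2, 3.1)))
  expect_false(any(same$significant))

  apart <- fisher_lsd(list(lo = c(-0.1, 0, 0.1), hi = c(9.9, 10, 10.1)))
  expect_true(all(apart$significant))

  # middle group equidistant from the outer two: symmetric outer p values
  sym <- fisher_lsd(list(a = c(0, 1, -1), b = c(5, 6, 4), c = c(10, 11, 9)))
  p_ab <- sym$p[sym$group1 == "a" & sym$group2 == "b"]
  p_bc <- sym$p[sym$group1 == "b" & sym$group2 == "c"]
  expect_equal(p_ab, p_bc, tolerance = 1e-12)
})
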