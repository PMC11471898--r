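test_that("amoA abundance is reads per bp, optionally depth-normalised", {
  expect_equal(amoa_relative_abundance(0, 900), 0)
  expect_equal(amoa_relative_abundance(900, 900), 1)
  # shorter gene, same reads: proportionally higher abundance
  expect_equal(amoa_relative_abundance(1000, 500),
               2 * amoa_relative_abundance(1000, 1000))
  expect_equal(amoa_relative_abundance(1000, 500, total_mapped_reads = 1e6),
               2e-6)
  expect_error(amoa_relative_abundance(10, 0), "gene_length")
})

test_that("MAG abundance is its contigs' coverage share of the sample", {
  expect_equal(mag_relative_abundance(c(10, 5), 300), 5.0)
  expect_equal(mag_relative_abundance(c(50, 50), 100), 100)
  expect_error(mag_relative_abundance(c(1, 2), 0), "total")
})

test_that("MAG percentages over a contig partition sum to exactly 100", {
  set.seed(21)
  for (i in 1:10) {
    cov <- runif(50, 0.1, 40)
    bins <- split(cov, sample(1:6, 50, replace = TRUE))
    pct <- vapply(bins, mag_relative_abundance,
                  total_coverage_all_contigs = sum(cov), numeric(1))
    expect_equal(sum(pct), 100, tolerance = 1e-12)
  }
})

test_that("fold change reproduces reported month-15-to-39 increases", {
  expect_equal(fold_change(0.02, 0.7)$fold, 35.0)
  expect_equal(fold_change(0.3, 3.2)$fold, 10.6667, tolerance = 1e-4)
  expect_equal(fold_change(1.7, 1.7)$fold, 1)
  z <- fold_change(0, 0.5)
  expect_true(z$undefined)
  # reciprocity
  set.seed(3)
  a <- runif(10, 0.01, 5); b <- runif(10, 0.01, 5)
  expect_equal(mapply(function(x, y) fold_change(x, y)$fold, a, b) *
                 mapply(function(x, y) fold_change(x, y)$fold, b, a),
               rep(1, 10))
})

test_that("Pearson r matches hand computation and its affine invariances", {
  # Sxy/sqrt(Sxx*Syy) = 8/10
  expect_equal(pearson_correlation(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
  x <- c(1, 3, 4, 7)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(x, -x)$r, -1.0)
  set.seed(5)
  y <- rnorm(8); x8 <- rnorm(8)
  base <- pearson_correlation(x8, y)
  expect_equal(pearson_correlation(3 * x8 + 2, y)$r, base$r)
  expect_equal(pearson_correlation(-2 * x8, y)$r, -base$r)
  expect_true(abs(base$r) <= 1)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("abundance-covariate correlations pair same-month observations", {
  sim <- simulate_abundance_series(35, noise_sd = 0, entity = "Nitrosocosmicus")
  res <- correlate_abundance(sim$abundance, sim$covariates)
  # linear rise vs linear PS rise: r = +1; vs declining NH4: r = -1
  expect_equal(res$r[res$covariate == "PS"], 1, tolerance = 1e-9)
  expect_equal(res$r[res$covariate == "NH4"], -1, tolerance = 1e-9)
  expect_true(all(res$n == 7))
})

test_that("pooled entities are summed before correlation and BH is optional", {
  s1 <- simulate_abundance_series(10, initial = 0.08, noise_sd = 0.1,
                                  seed = 1, entity = "cmx_mag_1")
  s2 <- simulate_abundance_series(20, initial = 0.04, noise_sd = 0.1,
                                  seed = 2, entity = "cmx_mag_2")
  ab <- rbind(s1$abundance, s2$abundance)
  res <- correlate_abundance(ab, s1$covariates,
                             pool = list(CMX_combined = c("cmx_mag_1", "cmx_mag_2")),
                             adjust = TRUE)
  expect_true("CMX_combined" %in% res$entity)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  pooled_series <- s1$abundance$value + s2$abundance$value
  expect_equal(res$r[res$entity == "CMX_combined" & res$covariate == "PS"],
               pearson_correlation(pooled_series, s1$covariates$PS)$r)
})
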