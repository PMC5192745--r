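test_that("expected g2 closed form matches hand arithmetic", {
  cfg <- sim_config(inbreeding = list(model = "mixture", pi = 0.2,
                                      f_high = 0.25), seed = 1)
  expect_equal(expected_g2(cfg), 0.01 / 0.9025, tolerance = 1e-9)
  expect_equal(expected_g2(cfg), 0.011080, tolerance = 1e-4)
  cfg0 <- sim_config(inbreeding = list(model = "constant", f = 0.3), seed = 1)
  expect_equal(expected_g2(cfg0), 0)
  cfg1 <- sim_config(inbreeding = list(model = "mixture", pi = 1,
                                       f_high = 0.25), seed = 1)
  expect_equal(expected_g2(cfg1), 0)
})

test_that("the functional-diversity flag lowers functional allele counts only", {
  cfg <- sim_config(functional_allele_factor = 0.5, seed = 5)
  expect_equal(cfg$alleles_per_locus[1:14],
               sim_config(seed = 5)$alleles_per_locus[1:14])
  expect_true(all(cfg$alleles_per_locus[15:26] <
                    sim_config(seed = 5)$alleles_per_locus[15:26]))
  expect_true(all(cfg$alleles_per_locus >= 2))
  expect_error(sim_config(functional_allele_factor = 0, seed = 1),
               "functional_allele_factor")
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_per_year = 40, years = 2010:2012, n_loci = 6,
                    n_neutral = 3, seed = 123)
  s1 <- suppressMessages(simulate_dataset(cfg))
  s2 <- suppressMessages(simulate_dataset(cfg))
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$weather, s2$weather)
  expect_identical(s1$truth, s2$truth)
  # and a different seed changes the data
  cfg2 <- sim_config(n_per_year = 40, years = 2010:2012, n_loci = 6,
                     n_neutral = 3, seed = 124)
  s3 <- suppressMessages(simulate_dataset(cfg2))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("simulated weather respects its own seasonal calibration", {
  cfg <- sim_config(seed = 31)
  w <- simulate_weather(cfg, years = 2008:2010)
  expect_true(all(w$tmax >= w$tmin))
  expect_true(all(w$precip >= 0))
  mo <- as.integer(format(w$date, "%m"))
  jul_mean <- mean((w$tmin + w$tmax)[mo == 7] / 2)
  jan_mean <- mean((w$tmin + w$tmax)[mo == 1] / 2)
  expect_gt(jul_mean, 22); expect_lt(jul_mean, 28)
  expect_gt(jan_mean, 2); expect_lt(jan_mean, 8)
  # same seed -> identical series; zero rain probability -> dry windows
  expect_identical(w, simulate_weather(cfg, years = 2008:2010))
  cfg_dry <- sim_config(weather = list(tmean_jan = 5, tmean_jul = 25,
                                       dhr_winter = 5, dhr_summer = 9,
                                       temp_sd = 2.5, rain_prob = 0,
                                       rain_shape = 0.8, rain_scale = 8.5,
                                       rain_year_sd = 0.35), seed = 8)
  wd <- simulate_weather(cfg_dry, years = 2008:2009)
  expect_equal(harshness_metrics(wd, 2008)$accumulated_precip, 0)
})

test_that("genotypes carry the configured inbreeding structure", {
  set.seed(60)
  freqs <- replicate(8, {p <- rexp(8); p / sum(p)}, simplify = FALSE)
  # outbred: per-locus H_O approaches E_l
  G0 <- simulate_genotypes(5000, freqs = freqs, f = 0)
  ms <- marker_summary(G0)
  for (j in 1:8) {
    se <- sqrt(ms$E_l[j] * (1 - ms$E_l[j]) / 5000)
    expect_lt(abs(ms$H_O[j] - (1 - sum(freqs[[j]]^2))), 3 * se + 1e-3)
  }
  # inbred fraction: H_O shrinks by (1 - f) and f correlates negatively
  # with realized multilocus heterozygosity
  f <- ifelse(runif(4000) < 0.3, 0.4, 0)
  G1 <- simulate_genotypes(4000, freqs = freqs, f = f)
  mlh <- rowMeans(is_het(G1))
  expect_lt(cor(f, mlh), -0.3)
  expect_lt(mean(mlh), mean(marker_summary(G0)$H_O))
})

test_that("recruitment generator saturates, nulls out and is recoverable", {
  cfg <- sim_config(recruitment = list(beta0 = 10, beta0_precip_slope = 0,
                                       beta1_base = 0,
                                       beta1_precip_slope = 0), seed = 3)
  het <- runif(2000, 0.4, 1)
  expect_equal(mean(simulate_recruitment(het, 0, cfg, seed = 1)), 1)

  cfg0 <- sim_config(recruitment = list(beta0 = 0, beta0_precip_slope = 0,
                                        beta1_base = 0,
                                        beta1_precip_slope = 0), seed = 3)
  set.seed(70)
  het0 <- runif(5000, 0.4, 1)
  r <- simulate_recruitment(het0, 0, cfg0, seed = 2)
  expect_lt(abs(cor(het0, r)), 0.05)

  # slope recovery: mean fitted slope near the generating slope 8
  cfg8 <- sim_config(recruitment = list(beta0 = 0, beta0_precip_slope = 0,
                                        beta1_base = 8,
                                        beta1_precip_slope = 0), seed = 3)
  set.seed(44)
  est <- replicate(50, {
    het <- runif(400, 0.4, 1)
    y <- simulate_recruitment(het, 0, cfg8)
    unname(fit_logistic(y, matrix(het, dimnames = list(NULL, "het")))$coefficients["het"])
  })
  expect_lt(abs(mean(est) - 8), 3 * sd(est) / sqrt(50))
})

test_that("simulated capture histories reproduce their recruitment codes", {
  cfg <- sim_config(n_per_year = 50, years = 2010:2013, n_loci = 8,
                    n_neutral = 4, seed = 91)
  sim <- suppressMessages(simulate_dataset(cfg))
  ind <- sim$individuals
  rd <- suppressMessages(derive_recruitment(ind[, setdiff(names(ind), "recruited")]))
  expect_equal(rd$recruited, ind$recruited)
  # every individual in the genotype matrix and vice versa
  expect_setequal(unique(ind$individual_id), sim$genotypes$ids)
  # truth aligns with the analysis-side heterozygosity
  het <- het_estimates(sim$genotypes, sim$panel)
  expect_gt(cor(sim$truth$het_true,
                het$het_total[match(names(sim$truth$het_true),
                                    het$individual_id)]), 0.99)
  expect_lt(cor(sim$truth$f, sim$truth$het_true), 0)
})
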