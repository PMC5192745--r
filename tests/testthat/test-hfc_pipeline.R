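make_ind_year <- function(n, year = 2010, seed = 1) {
  set.seed(seed)
  data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    year = year, plot = sample(c("A", "B"), n, TRUE),
    sex = sample(c("M", "F"), n, TRUE), age = sample(1:4, n, TRUE),
    origin = sample(c("local", "immigrant"), n, TRUE),
    body_mass = rnorm(n, 11, 0.5), tarsus = rnorm(n, 16.5, 0.5),
    wing = rnorm(n, 66, 2), laying_date = round(rnorm(n, 100, 7)),
    fledging_success = rpois(n, 5),
    pair_id = paste0("p", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]),
    stringsAsFactors = FALSE)
}

test_that("body condition residuals have OLS properties", {
  ind <- make_ind_year(40)
  bc <- body_condition(ind)
  expect_equal(sum(bc), 0, tolerance = 1e-10)
  # mass an exact linear function of tarsus -> all residuals 0
  ind2 <- ind; ind2$body_mass <- 2 * ind2$tarsus
  expect_equal(body_condition(ind2), rep(0, 40), tolerance = 1e-8)
  # mass independent of predictors: residuals ~ centered mass
  ind3 <- ind; ind3$body_mass <- rnorm(40, 20, 3)
  expect_equal(cor(body_condition(ind3), ind3$body_mass - mean(ind3$body_mass)),
               1, tolerance = 0.2)
  # collinear predictors are rejected with the pair named
  ind4 <- ind; ind4$wing <- 3 * ind4$tarsus
  expect_error(body_condition(ind4), "collinear.*wing.*tarsus|collinear.*tarsus.*wing")
})

test_that("Holm step-down matches the hand example and the brute-force rule", {
  hs <- holm_stepdown(c(0.001, 0.03, 0.04), alpha = 0.05)
  expect_equal(hs$threshold, c(0.05 / 3, 0.05 / 2, 0.05))
  expect_equal(hs$significant, c(TRUE, FALSE, FALSE))

  set.seed(19)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(holm_stepdown(p, 0.05)$significant, holm_brute(p, 0.05))
  }
})

test_that("single-locus scan reports effect sizes and skips monomorphic loci", {
  set.seed(23)
  n <- 300
  yd <- make_ind_year(n)
  h <- cbind(l1 = rbinom(n, 1, 0.6), l2 = rbinom(n, 1, 0.5),
             l3 = rep(1L, n))
  rownames(h) <- yd$individual_id
  yd$recruited <- rbinom(n, 1, plogis(-1 + 2.5 * h[, "l1"]))
  expect_warning(
    sc <- single_locus_scan(yd, h, covariates = FALSE, random = FALSE),
    "monomorphic.*l3")
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$effect_size_r, sc$z / sqrt(sc$n))
  expect_true(all(abs(sc$effect_size_r) <= 1))
  # Holm flags consistent with sorted p ordering
  o <- order(sc$p_raw)
  expect_true(all(diff(sc$significant_after_correction[o] * 1) <= 0))
  # the causal locus has the larger effect size
  expect_gt(abs(sc$effect_size_r[sc$locus == "l1"]),
            abs(sc$effect_size_r[sc$locus == "l2"]))
})

test_that("effect-size model recovers exact linear structure", {
  stats <- data.frame(locus = paste0("l", 1:8), A_R = c(3:10),
                      H_O = c(0.5, 0.62, 0.55, 0.7, 0.8, 0.6, 0.75, 0.85))
  panel <- data.frame(locus_name = paste0("l", 1:8), chromosome = "1",
                      category = rep(c("neutral", "functional"), 4))
  scan <- data.frame(locus = paste0("l", 1:8),
                     effect_size_r = 0.01 * (3:10))
  tab <- effect_size_model(scan, stats, panel)
  expect_equal(tab$estimate[tab$term == "A_R"], 0.01, tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "categoryneutral"], 0,
               tolerance = 1e-8)

  # constant effect sizes: all slopes 0
  scan0 <- scan; scan0$effect_size_r <- 0.1
  tab0 <- effect_size_model(scan0, stats, panel)
  expect_equal(tab0$estimate[tab0$term != "(Intercept)"], c(0, 0, 0),
               tolerance = 1e-10)

  # permuting category labels flips the category contrast only
  set.seed(2)
  scan2 <- scan; scan2$effect_size_r <- 0.01 * (3:10) + rnorm(8, 0, 0.01)
  t1 <- effect_size_model(scan2, stats, panel)
  panel_sw <- panel; panel_sw$category <- ifelse(panel$category == "neutral",
                                                "functional", "neutral")
  t2 <- effect_size_model(scan2, stats, panel_sw)
  expect_equal(t2$estimate[t2$term == "categoryneutral"],
               -t1$estimate[t1$term == "categoryneutral"], tolerance = 1e-10)
  expect_equal(t2$estimate[t2$term == "A_R"], t1$estimate[t1$term == "A_R"],
               tolerance = 1e-10)
})

test_that("year datasets join, delete and log; multilocus HFC runs end to end", {
  cfg <- sim_config(n_per_year = 60, years = 2010:2012, n_loci = 10,
                    n_neutral = 5, seed = 17)
  sim <- suppressMessages(simulate_dataset(cfg))
  het <- het_estimates(sim$genotypes, sim$panel)
  yd <- suppressMessages(year_dataset(sim$individuals, het, year = 2010))
  expect_true(all(!is.na(yd$recruited)))
  expect_true(all(c("het_total", "body_condition", "pair_id") %in% names(yd)))
  expect_error(run_multilocus_hfc(yd[1:10, ]), "modeled rows")

  avg <- suppressWarnings(run_multilocus_hfc(yd, random = FALSE))
  expect_s3_class(avg, "hetfit_avg")
  # forced factors appear in every model, hence always in the table; the
  # het term is a candidate and may be absent from the equivalent set
  expect_true(all(c("plotB", "sexM", "originlocal") %in% avg$term))
  expect_true("het_total" %in% attr(avg, "modelset")$candidate_terms)
  expect_true(all(diff(avg$sum_weights) <= 1e-12))
  expect_true(all(avg$ci_low < avg$ci_high))

  # univariate het-only fit agrees in sign with the averaged coefficient
  # when the simulated effect is strong
  cfg2 <- sim_config(n_per_year = 250, years = 2011:2012,
                     recruitment = list(beta0 = -0.4, beta0_precip_slope = 0,
                                        beta1_base = 8,
                                        beta1_precip_slope = 0),
                     seed = 29)
  sim2 <- suppressMessages(simulate_dataset(cfg2))
  het2 <- het_estimates(sim2$genotypes, sim2$panel)
  yd2 <- suppressMessages(year_dataset(sim2$individuals, het2, year = 2011))
  uni <- univariate_hfc(yd2)
  avg2 <- suppressWarnings(run_multilocus_hfc(yd2))
  expect_gt(uni$estimate, 0)
  expect_gt(avg2$estimate[avg2$term == "het_total"], 0)

  # post-hoc interaction checks: no het x plot / het x sex structure was
  # generated, so neither interaction should be (strongly) significant
  ia <- hfc_interactions(yd2, random = FALSE)
  expect_equal(ia$interaction, c("het_total x plot", "het_total x sex"))
  expect_true(all(is.finite(ia$z)))
  expect_gt(min(ia$p), 0.001)
})
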