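test_that("logistic fits reproduce closed forms", {
  # intercept-only with 3 successes of 6: logit(0.5) = 0
  f0 <- fit_logistic(c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(f0$coefficients), 0, tolerance = 1e-12)

  # 2x2 table: exposed 30/50 events, unexposed 10/50 -> slope log 6
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  x <- c(rep(1, 50), rep(0, 50))
  f <- fit_logistic(y, matrix(x, dimnames = list(NULL, "exposed")))
  expect_equal(unname(f$coefficients["exposed"]), log(6), tolerance = 1e-8)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(10 / 40),
               tolerance = 1e-8)
  expect_true(f$converged)
  expect_equal(f$k_params, 2L)
})

test_that("aliased columns are dropped and separation is an error", {
  set.seed(2)
  x <- rnorm(40)
  X <- cbind(a = x, b = 2 * x)
  y <- rbinom(40, 1, plogis(x))
  expect_warning(f <- fit_logistic(y, X), "aliased")
  expect_equal(f$terms, "a")

  xs <- c(rep(0, 10), rep(1, 10))
  ys <- xs  # perfectly separated
  expect_error(fit_logistic(ys, matrix(xs, dimnames = list(NULL, "xs"))),
               "separation")
})

test_that("random-intercept fit collapses to the fixed fit when SD is 0", {
  set.seed(31)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.3 + x))
  g <- rep(1:100, each = 2)
  ffix <- fit_logistic(y, matrix(x, dimnames = list(NULL, "x")))
  fmix <- fit_logistic(y, matrix(x, dimnames = list(NULL, "x")), groups = g)
  expect_equal(fmix$random_intercept_sd, 0, tolerance = 1e-4)
  expect_equal(fmix$loglik, ffix$loglik, tolerance = 1e-6)
  expect_equal(fmix$k_params, ffix$k_params + 1L)
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-10, k = 2, n = 23), 24.6)
  expect_equal(aicc(-10, k = 0, n = 23), 20)
  expect_error(aicc(-10, k = 4, n = 5), "AICc undefined")
  # monotone decreasing in loglik at fixed (k, n)
  expect_lt(aicc(-9, k = 2, n = 23), aicc(-10, k = 2, n = 23))
})

test_that("Akaike weights and top-set structure are correct", {
  aw <- akaike_weights(c(100, 102))
  expect_equal(aw$weights, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(aw$weights), 1)

  set.seed(4)
  d <- data.frame(y = rbinom(60, 1, 0.4), a = rnorm(60), b = rnorm(60),
                  c = rnorm(60))
  ms1 <- model_selection(d, "y", candidate_terms = "a")
  expect_equal(nrow(ms1$table), 2L)
  ms3 <- suppressWarnings(model_selection(d, "y", c("a", "b", "c")))
  expect_equal(nrow(ms3$table), 8L)
  expect_equal(min(ms3$table$delta), 0)
  expect_equal(sum(ms3$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(ms3$table$delta) >= 0))
})

test_that("model averaging matches the hand-worked USE example", {
  avg <- unconditional_average(est = c(1, 2), se = c(0.5, 0.5),
                               w = c(0.6, 0.4))
  expect_equal(avg$estimate, 1.4)
  expect_equal(avg$use, 0.6 * sqrt(0.25 + 0.16) + 0.4 * sqrt(0.25 + 0.36),
               tolerance = 1e-12)
  expect_equal(avg$use, 0.6966, tolerance = 1e-4)

  # single-model averaging is the identity on (estimate, SE)
  set.seed(12)
  a <- rnorm(80)
  d <- data.frame(y = rbinom(80, 1, plogis(2 * a)), a = a)
  ms <- model_selection(d, "y", "a")
  ms$top_set <- which.min(ms$table$delta)  # restrict to the best model
  av <- model_average(ms)
  best <- ms$fits[[ms$top_set]]
  expect_equal(av$estimate[av$term == "a"], unname(best$coefficients["a"]))
  expect_equal(av$use[av$term == "a"], unname(best$se["a"]))
  expect_equal(av$sum_weights, 1)
  # significance flag mirrors the CI
  expect_equal(av$significant, av$ci_low > 0 | av$ci_high < 0)
})

test_that("MLH-vs-SLH F-ratio test behaves under null and local effects", {
  expect_error(mlh_vs_slh_ftest(rnorm(50), NULL, rnorm(50),
                                matrix(rnorm(50), 50, 1)), ">= 2 SLH loci")
  set.seed(77)
  L <- 10
  # null: outcome depends on MLH only -> SLH adds nothing beyond it
  pvals <- replicate(200, {
    h <- matrix(rbinom(200 * L, 1, 0.6), 200, L)
    hz <- scale(h)
    mlh <- rowMeans(h)
    y <- rbinom(200, 1, plogis(-2 + 3 * mlh))
    mlh_vs_slh_ftest(y, NULL, mlh, hz)$p
  })
  expect_gte(mean(pvals > 0.05), 0.9)

  # deviance-based analogue agrees qualitatively on a null draw
  set.seed(5)
  h <- matrix(rbinom(200 * L, 1, 0.6), 200, L)
  mlh <- rowMeans(h)
  y <- rbinom(200, 1, plogis(-2 + 3 * mlh))
  fd <- mlh_vs_slh_ftest(y, NULL, mlh, scale(h), type = "deviance")
  expect_true(is.finite(fd$F) && fd$p > 0.001)
  expect_equal(fd$df1, L - 1)

  # one locus with a strong private effect: the SLH model must win
  pow <- replicate(50, {
    h <- matrix(rbinom(400 * L, 1, 0.6), 400, L)
    hz <- scale(h)
    mlh <- rowMeans(h)
    y <- rbinom(400, 1, plogis(-1.5 + 3 * h[, 1]))
    mlh_vs_slh_ftest(y, NULL, mlh, hz)$p < 0.05
  })
  expect_gte(mean(pow), 0.8)
})
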