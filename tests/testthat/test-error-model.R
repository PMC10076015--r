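test_that("empirical percentiles follow the Hazen convention and clamp", {
  r <- percentile_ref(c(10, 20, 30))
  expect_equal(empirical_percentile(r, 20), 0.5)
  expect_equal(empirical_percentile(r, 5), 1 / 6)
  expect_equal(empirical_percentile(r, 35), 5 / 6)
  set.seed(2)
  draws <- rnorm(303, 2400, 490)
  r2 <- percentile_ref(draws)
  expect_equal(empirical_percentile(r2, max(draws)), (303 - 0.5) / 303)
  expect_equal(empirical_percentile(r2, min(draws)), 0.5 / 303)
  # monotone and bounded
  x <- sort(runif(200, 500, 4500))
  p <- empirical_percentile(r2, x)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(percentile_ref(numeric(0)))
})

test_that("the mean-error polynomial evaluates correctly and checks p", {
  expect_equal(mean_error(c(0, 0, 0), 0.7), 0)
  expect_equal(mean_error(c(-100, -500), 0.5), -350)
  expect_equal(mean_error(c(0, 0, 0, 1), 0.5), 0.125)
  expect_error(mean_error(c(1, 1), 1.2), "\\[0, 1\\]")
  expect_error(mean_error(c(1, 1), -0.1), "\\[0, 1\\]")
})

test_that("polynomial fitting recovers exact and noisy truths", {
  p <- seq(0.05, 0.95, length.out = 20)
  cf <- fit_mean_error(p, 3 - 7 * p, 1)
  expect_equal(unname(cf), c(3, -7), tolerance = 1e-10)
  cf2 <- fit_mean_error(p, rep(4.2, 20), 3)
  expect_equal(unname(cf2[1]), 4.2, tolerance = 1e-8)
  expect_equal(unname(cf2[-1]), rep(0, 3), tolerance = 1e-7)
  expect_error(fit_mean_error(rep(0.5, 10), rnorm(10), 2), "rank-deficient")

  # with K+1 = n distinct points the fit interpolates; oracle: direct solve
  p4 <- c(0.1, 0.3, 0.6, 0.9)
  y4 <- c(2, -1, 4, 0)
  cf3 <- fit_mean_error(p4, y4, 3)
  oracle <- solve(outer(p4, 0:3, `^`), y4)
  expect_equal(unname(cf3), oracle, tolerance = 1e-8)
  expect_equal(mean_error(cf3, p4), y4, tolerance = 1e-8)

  # noisy cubic: agrees with the lm oracle, and recovery within 3 SE
  set.seed(77)
  p5 <- runif(1000)
  truth <- c(5, -40, 10, 30)
  y5 <- mean_error(truth, p5) + rnorm(1000, 0, 8)
  cf5 <- fit_mean_error(p5, y5, 3)
  lm_fit <- lm(y5 ~ p5 + I(p5^2) + I(p5^3))
  expect_equal(unname(cf5), unname(coef(lm_fit)), tolerance = 1e-8)
  se <- summary(lm_fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(cf5 - truth) < 3 * se))
})

test_that("cross-validated order selection picks the generating order", {
  p <- seq(0.01, 0.99, length.out = 100)
  set.seed(5)
  expect_equal(select_order_cv(p, 2 - 3 * p), 1L, ignore_attr = TRUE)
  expect_equal(select_order_cv(p, rnorm(100), k_range = 2), 2L,
               ignore_attr = TRUE)
  # selected order attains the minimal CV-MSE by construction
  k <- select_order_cv(p, 1 + p - 4 * p^3 + rnorm(100, 0, 0.5))
  expect_equal(attr(k, "cv_mse")[[paste0("K", k)]], min(attr(k, "cv_mse")))
  # strong cubic with moderate noise: majority selection over seeds
  hits <- 0
  for (s in 1:25) {
    set.seed(1000 + s)
    p3 <- runif(303)
    y3 <- mean_error(c(0, -500, 0, 900), p3) + rnorm(303, 0, 100)
    if (select_order_cv(p3, y3) == 3L) hits <- hits + 1
  }
  expect_gt(hits, 12)
  expect_error(select_order_cv(p[1:5], rnorm(5), folds = 10), "folds")
})

test_that("sigma estimation uses the n - (K+1) denominator", {
  p <- seq(0.05, 0.95, length.out = 30)
  cf <- fit_mean_error(p, 1 - 2 * p + 3 * p^2, 2)
  expect_lt(estimate_sigma(p, 1 - 2 * p + 3 * p^2, cf), 1e-8)
  expect_equal(estimate_sigma(c(0.2, 0.8), c(-1, 1), c(0)), sqrt(2))
  expect_error(estimate_sigma(c(0.2, 0.8), c(-1, 1), c(0, 1)), "more observations")
})

test_that("Goldfeld-Quandt discards the printed central band and matches var.test", {
  set.seed(8)
  gq <- goldfeld_quandt(rnorm(303), rnorm(303), 0.2)
  expect_equal(gq$n_discarded, 61L)
  expect_equal(gq$n_low + gq$n_high, 242L)

  # symmetric construction: identical spread in both tails
  e <- c(-2, -1, 1, 2, 0, 0, -2, -1, 1, 2)
  gq2 <- goldfeld_quandt(e, seq_along(e), 0.2)
  expect_equal(gq2$statistic, 1)

  # oracle: var.test on the same low/high groups
  err <- rnorm(100)
  ord <- rnorm(100)
  gq3 <- goldfeld_quandt(err, ord, 0.2)
  e_sorted <- err[order(ord)]
  low <- e_sorted[1:gq3$n_low]
  high <- e_sorted[(100 - gq3$n_high + 1):100]
  vt <- var.test(if (var(high) >= var(low)) high else low,
                 if (var(high) >= var(low)) low else high)
  expect_equal(gq3$statistic, unname(vt$statistic), tolerance = 1e-12)
  expect_equal(gq3$p_value, vt$p.value, tolerance = 1e-12)
})

test_that("Goldfeld-Quandt holds its type-I error under homoskedasticity", {
  set.seed(12)
  rejections <- 0
  for (i in 1:400) {
    ord <- rnorm(150)
    err <- rnorm(150) # variance unrelated to the ordering
    if (goldfeld_quandt(err, ord, 0.2)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / 400
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the assembled error model behaves on degenerate and typical cohorts", {
  co <- make_cohort(120, seed = 14)
  co$ei_sr_kcal <- co$ei_bio_kcal # perfect reporting
  set.seed(3)
  em <- fit_error_model(co, "ei")
  expect_lt(max(abs(em$coefficients)), 1e-8)
  expect_lt(em$sigma, 1e-8)
  expect_s3_class(em, "error_model")
  expect_equal(em$order, length(em$coefficients) - 1L)

  co2 <- make_cohort(303, seed = 15)
  set.seed(4)
  em2 <- fit_error_model(co2, "ei")
  expect_true(em2$order %in% 1:5)
  expect_gt(em2$sigma, 0)
  # decreasing reporting error in intake: negative fitted linear trend
  expect_lt(mean_error(em2, 0.9), mean_error(em2, 0.1))
})
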