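test_that("the SR-biomarker correlation identity inverts the printed SDs", {
  expect_equal(derive_sr_bio_correlation(1, 1, sqrt(2)), 0)
  expect_error(derive_sr_bio_correlation(1, 1, 0), "inconsistent")
  # energy values: frozen from (sd_sr^2 + sd_bio^2 - sd_bias^2) / (2 sd_sr sd_bio)
  expect_equal(derive_sr_bio_correlation(783.4, 492.8, 811.0), 0.2575,
               tolerance = 1e-3)
  expect_error(derive_sr_bio_correlation(-1, 1, 1), "positive")
})

test_that("linear mean-error calibration solves the three moment targets", {
  cal <- calibrate_linear_mu(0, 1, 0)
  expect_equal(unname(cal$coefficients), c(0, 0))
  expect_equal(cal$sigma, 1)
  # the slope sign follows the target correlation
  for (rho in c(-0.6, -0.2, 0.3, 0.7)) {
    cal <- calibrate_linear_mu(-100, 50, rho)
    expect_equal(sign(cal$coefficients[["m1"]]), sign(rho))
    # moment checks: mean and variance of m0 + m1 P + noise, P ~ U(0,1)
    expect_equal(cal$coefficients[["m0"]] + cal$coefficients[["m1"]] / 2, -100)
    expect_equal(cal$coefficients[["m1"]]^2 / 12 + cal$sigma^2, 50^2,
                 tolerance = 1e-10)
  }
  expect_error(calibrate_linear_mu(0, 1, 0.999), "feasible")
})

test_that("linear calibration is self-consistent under simulation", {
  cal <- calibrate_linear_mu(-350, 811, -0.359)
  set.seed(61)
  n <- 100000
  bio <- rnorm(n, 2400.3, 492.8)
  p <- empirical_percentile(percentile_ref(bio), bio)
  e <- mean_error(cal$coefficients, p) + rnorm(n, 0, cal$sigma)
  expect_equal(mean(e), -350, tolerance = 5 / 350, ignore_attr = TRUE)
  expect_equal(sd(e), 811, tolerance = 0.01)
  expect_equal(cor(e, bio), -0.359, tolerance = 0.01 / 0.359)
})

test_that("higher-order calibration keeps the declared structure", {
  # Legendre-normal covariance constants against a grid-quadrature oracle
  Lraw <- goldbergsim:::.shifted_legendre
  z <- seq(-10, 10, length.out = 400001)
  dz <- z[2] - z[1]
  for (j in 1:5) {
    lj <- drop(cbind(1, outer(pnorm(z), 1:5, `^`)) %*% Lraw[j + 1, ])
    kappa <- sum(lj * z * dnorm(z)) * dz
    expect_equal(goldbergsim:::.legendre_kappa[j], kappa, tolerance = 1e-6)
  }
  for (k in c(1, 3, 5)) {
    cal <- calibrate_mu(-300, 800, -0.4, order = k)
    expect_length(cal$coefficients, k + 1)
    expect_gte(cal$sigma, 0)
    # decreasing overall trend for a negative correlation target
    pg <- seq(0.005, 0.995, length.out = 200)
    mu <- mean_error(cal$coefficients, pg)
    expect_lt(mean(mu[pg > 0.5]), mean(mu[pg < 0.5]))
    expect_equal(mean(mu), -300, tolerance = 1e-6)
  }
  expect_error(calibrate_mu(0, 1, 0.9999, order = 3), "inconsistent")
})

test_that("generated cohorts are positive and hit their calibration targets", {
  co <- make_cohort(30000, seed = 23)
  intake_cols <- c("ffm_kg", vapply(nutrients4, bio_col, ""),
                   vapply(nutrients4, sr_col, ""))
  expect_true(all(co[, intake_cols] > 0))
  cfg <- default_config()
  for (i in 1:4) {
    nu <- cfg$nutrients$nutrient[i]
    bio <- co[[bio_col(nu)]]
    e <- co[[sr_col(nu)]] - bio
    n <- nrow(co)
    expect_equal(mean(bio), cfg$nutrients$bio_mean[i],
                 tolerance = 4 * cfg$nutrients$bio_sd[i] / sqrt(n) /
                   cfg$nutrients$bio_mean[i])
    expect_equal(mean(e), cfg$nutrients$bias_mean[i],
                 tolerance = abs(4 * cfg$nutrients$bias_sd[i] / sqrt(n) /
                                   cfg$nutrients$bias_mean[i]))
    # reporting error declines with biomarker intake (negative correlation)
    expect_lt(cor(e, bio), -0.2)
  }
})

test_that("outcome generation recovers its linear truths", {
  co <- make_cohort(20000, seed = 29)
  cfg <- default_config()
  for (oc in c("bw", "vo2")) {
    tr <- cfg$outcome_truth[[oc]]
    fit <- lm(co[[goldbergsim:::outcome_columns(oc)]] ~ co[[bio_col(tr$nutrient)]])
    se <- summary(fit)$coefficients[2, "Std. Error"]
    expect_lt(abs(coef(fit)[2] - tr$a1), 3 * se)
  }
})

test_that("zero error truths give exact self-reports", {
  cfg <- default_config()
  for (nu in nutrients4) {
    cfg$mu_truth[[nu]]$coefficients[] <- 0
    cfg$mu_truth[[nu]]$sigma <- 0
  }
  set.seed(3)
  co <- generate_cohort(cfg, n = 200)
  for (nu in nutrients4)
    expect_identical(co[[sr_col(nu)]], co[[bio_col(nu)]])
})

test_that("the fixture cohort is small and deterministic", {
  f1 <- fixture_cohort()
  f2 <- fixture_cohort()
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 10)
  expect_named(f1, cohort_columns())
})
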