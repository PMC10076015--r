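test_that("closed-form OLS agrees with the lm/confint oracle", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- rnorm(n, 10, 3)
    y <- 1 + 0.5 * x + rnorm(n)
    fit <- ols_fit(x, y)
    lmf <- lm(y ~ x)
    ci <- confint(lmf)["x", ]
    expect_equal(fit$beta_hat, unname(coef(lmf)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(lmf)[1]), tolerance = 1e-10)
    expect_equal(fit$ci_low, unname(ci[1]), tolerance = 1e-10)
    expect_equal(fit$ci_high, unname(ci[2]), tolerance = 1e-10)
    expect_equal(fit$sigma, summary(lmf)$sigma, tolerance = 1e-10)
  }
})

test_that("OLS handles exact and degenerate configurations", {
  fit <- ols_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$beta_hat, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$ci_low, 2)
  expect_equal(fit$ci_high, 2)
  x <- scale(rnorm(50))[, 1]
  expect_equal(ols_fit(x, x)$beta_hat, 1, tolerance = 1e-12)
  expect_error(ols_fit(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("leave-one-out slopes match the brute-force oracle", {
  set.seed(17)
  x <- rnorm(40, 5, 2)
  y <- 2 - 0.7 * x + rnorm(40)
  fast <- loo_slopes(x, y)
  brute <- vapply(1:40, function(i) ols_fit(x[-i], y[-i])$beta_hat, numeric(1))
  expect_equal(fast, brute, tolerance = 1e-10)
})

test_that("outcome-model fitting recovers generating parameters", {
  om <- fit_outcome_model(
    data.frame(ei_bio_kcal = c(1, 2, 3), bw_kg = c(2, 4, 6),
               ei_sr_kcal = 1, ffm_kg = 1), "ei", "bw")
  expect_equal(om$a0, 0)
  expect_equal(om$a1, 2)
  expect_equal(om$eta, 0)

  set.seed(53)
  n <- 10000
  bio <- rnorm(n, 2400, 500)
  co <- data.frame(ei_bio_kcal = bio,
                   bw_kg = 10 + 0.005 * bio + rnorm(n, 0, 5))
  om2 <- fit_outcome_model(co, "ei", "bw")
  se <- summary(lm(bw_kg ~ ei_bio_kcal, co))$coefficients[2, "Std. Error"]
  expect_lt(abs(om2$a1 - 0.005), 3 * se)
  expect_equal(om2$eta, 5, tolerance = 0.05)

  # independent outcome: slope within 3 SE of zero
  co$indep <- rnorm(n)
  co$wc_cm <- rnorm(n, 92, 14)
  om3 <- fit_outcome_model(co, "ei", "wc")
  se3 <- summary(lm(wc_cm ~ ei_bio_kcal, co))$coefficients[2, "Std. Error"]
  expect_lt(abs(om3$a1), 3 * se3)
})

test_that("resampling preserves rows, reproduces under a seed, and is uniform", {
  one <- fixture_cohort()[1, ]
  rs <- resample_cohort(one, 5)
  expect_equal(nrow(rs), 5)
  expect_true(all(rs$id == one$id))

  co <- fixture_cohort()
  set.seed(10); a <- resample_cohort(co, 50)
  set.seed(10); b <- resample_cohort(co, 50)
  expect_identical(a, b)

  set.seed(11)
  big <- resample_cohort(co, 100000)
  freq <- table(factor(big$id, levels = co$id)) / 100000
  expect_true(all(abs(freq - 0.1) < 4 * sqrt(0.1 * 0.9 / 100000)))
  expect_error(resample_cohort(co, 0), "positive")
})

test_that("replicates with no reporting error reproduce the biomarker fits", {
  src <- make_cohort(303, seed = 71)
  ref <- percentile_ref(src$ei_bio_kcal)
  ems <- lapply(nutrients4, function(nu)
    error_model(c(0), 0, percentile_ref(src[[bio_col(nu)]]), nu))
  names(ems) <- nutrients4
  oms <- lapply(nutrients4, function(nu) {
    o <- lapply(outcomes6, function(oc) fit_outcome_model(src, nu, oc))
    names(o) <- outcomes6
    o
  })
  names(oms) <- nutrients4
  set.seed(5)
  rep1 <- generate_replicate(src, ems, oms, config = sim_config(sigma_scale = 0))
  wide <- reshape(rep1[, c("nutrient", "outcome", "estimator", "beta_hat")],
                  direction = "wide", idvar = c("nutrient", "outcome"),
                  timevar = "estimator")
  expect_equal(wide$beta_hat.SR, wide$beta_hat.BIO, tolerance = 1e-12)

  # eta_scale = 0: the biomarker fit recovers the generating slope exactly
  set.seed(6)
  rep2 <- generate_replicate(src, ems, oms,
                             config = sim_config(eta_scale = 0))
  for (i in which(rep2$estimator == "BIO"))
    expect_equal(rep2$beta_hat[i],
                 oms[[rep2$nutrient[i]]][[rep2$outcome[i]]]$a1,
                 tolerance = 1e-10)
})

test_that("the simulation engine is deterministic and bookkeeps rows", {
  src <- make_cohort(150, seed = 81)
  cfg <- sim_config(n_individuals = 40, n_replicates = 2, seed = 12)
  s1 <- run_simulation(src, cfg)
  s2 <- run_simulation(src, cfg)
  expect_identical(s1$results, s2$results)
  expect_equal(nrow(s1$results), 24 * 3 * 2)
  expect_named(s1$results, c("nutrient", "outcome", "estimator", "beta_hat",
                             "ci_low", "ci_high", "n_used", "replicate"))
  expect_true(all(s1$results$ci_low <= s1$results$beta_hat &
                    s1$results$beta_hat <= s1$results$ci_high, na.rm = TRUE))
})

test_that("sensitivity grids run over sample size", {
  src <- make_cohort(150, seed = 82)
  for (n in c(50, 100)) {
    sim <- run_simulation(src, sim_config(n_individuals = n, n_replicates = 2,
                                          nutrients = "ei", outcomes = "bw",
                                          seed = 1))
    expect_equal(unique(sim$results$n_used[sim$results$estimator == "BIO"]), n)
  }
})
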