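test_that("one-sample and Welch tests match hand-computed formulas", {
  r <- one_sample_t(c(-1, 0, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(one_sample_t(c(1, 2, 3), null_mean = 2)$t, 0)
  expect_error(one_sample_t(rep(2, 5)), "zero variance")

  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_lt(welch_t(c(0, 0, 0, 1e-6), c(1, 1, 1, 1 + 1e-6))$p, 1e-6)

  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), 1)
    y <- rnorm(sample(5:40, 1))
    # hand-rolled oracles
    t1 <- mean(x) / (sd(x) / sqrt(length(x)))
    p1 <- 2 * pt(-abs(t1), length(x) - 1)
    r1 <- one_sample_t(x)
    expect_equal(r1$t, t1, tolerance = 1e-10)
    expect_equal(r1$p, p1, tolerance = 1e-10)
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    tw <- (mean(x) - mean(y)) / sqrt(vx + vy)
    dfw <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    rw <- welch_t(x, y)
    expect_equal(rw$t, tw, tolerance = 1e-10)
    expect_equal(rw$p, 2 * pt(-abs(tw), dfw), tolerance = 1e-10)
  }
})

test_that("the whole-vs-accepted jackknife test handles degenerate splits", {
  r <- paired_jackknife_test(rnorm(10), rep(TRUE, 10))
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)

  # brute-force leave-one-out oracle
  set.seed(37)
  v <- rnorm(10)
  acc <- c(rep(TRUE, 6), rep(FALSE, 4))
  r2 <- paired_jackknife_test(v, acc)
  theta <- vapply(1:10, function(i) mean(v[-i]) - mean(v[-i][acc[-i]]),
                  numeric(1))
  se <- sqrt(9 / 10 * sum((theta - mean(theta))^2))
  expect_equal(r2$se, se, tolerance = 1e-12)
  expect_equal(r2$difference, mean(v) - mean(v[acc]))
  expect_error(paired_jackknife_test(v, c(TRUE, rep(FALSE, 9))), "more than 1")
})

test_that("mean-bias and group tables account for every participant", {
  co <- make_cohort(2000, seed = 101)
  suppressMessages({
    mb <- mean_bias_table(co)
    gc_ <- group_comparison_table(co)
  })
  expect_equal(nrow(mb), 4 * 3)
  expect_true(all(mb$p >= 0 & mb$p <= 1, na.rm = TRUE))
  all_rows <- mb[mb$group == "all", ]
  expect_true(all(all_rows$n == nrow(co)))
  expect_true(all(gc_$n_accepted + gc_$n_rejected == nrow(co)))
  expect_true(all(is.finite(gc_$t)))

  # the screen removes predominantly energy underreporters, so the
  # accepted-group mean energy bias sits much closer to zero; the other
  # nutrients barely move because the generator draws their reporting
  # noise independently of the energy noise
  m_all <- mb$mean_bias[mb$nutrient == "ei" & mb$group == "all"]
  m_acc <- mb$mean_bias[mb$nutrient == "ei" & mb$group == "accepted"]
  expect_lt(abs(m_acc), abs(m_all) / 3)
})

test_that("association-bias tables are exact under perfect reporting", {
  co <- make_cohort(200, seed = 103)
  for (nu in nutrients4) co[[sr_col(nu)]] <- co[[bio_col(nu)]]
  tab <- association_bias_table(co)
  expect_equal(nrow(tab), 24)
  expect_equal(tab$b, rep(0, 24), tolerance = 1e-10)
  # screening only removes rows, so beta_G stays on the biomarker value too
  expect_equal(tab$beta_sr, tab$beta_bio, tolerance = 1e-12)
})

test_that("association-bias jackknife CIs are deterministic and coherent", {
  co <- make_cohort(200, seed = 104)
  t1 <- association_bias_table(co)
  t2 <- association_bias_table(co)
  expect_identical(t1, t2)
  ok <- !t1$unstable
  expect_true(all(t1$b_lo[ok] <= t1$b[ok] & t1$b[ok] <= t1$b_hi[ok]))
  expect_true(all(t1$r_lo[ok] <= t1$r[ok] & t1$r[ok] <= t1$r_hi[ok]))

  # the three slopes come from the advertised row sets
  scr <- screen_cohort(co)
  acc <- scr$results$accepted
  row <- t1[t1$nutrient == "ei" & t1$outcome == "bw", ]
  expect_equal(row$beta_bio, ols_fit(co$ei_bio_kcal, co$bw_kg)$beta_hat)
  expect_equal(row$beta_sr, ols_fit(co$ei_sr_kcal, co$bw_kg)$beta_hat)
  expect_equal(row$beta_g,
               ols_fit(co$ei_sr_kcal[acc], co$bw_kg[acc])$beta_hat)
})

test_that("self-report attenuates the energy-weight association at scale", {
  co <- make_cohort(10000, seed = 107)
  tab <- association_bias_table(co)
  row <- tab[tab$nutrient == "ei" & tab$outcome == "bw", ]
  expect_lt(row$b, 0)
  expect_lt(row$b_hi, 0) # significantly below zero
})
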