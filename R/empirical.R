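#' One-sample t test
#'
#' Two-tailed Student's t test of whether the mean of `values` differs from
#' `null_mean`. Thin wrapper over [stats::t.test()] returning the statistic
#' and p-value.
#'
#' @param values numeric vector, at least 2 values with nonzero variance.
#' @param null_mean null hypothesis mean, default 0.
#' @return List with `t` and `p`.
#' @export
one_sample_t <- function(values, null_mean = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 observations")
  if (stats::var(values) == 0) stop("degenerate input: zero variance")
  tt <- stats::t.test(values, mu = null_mean)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Welch's two-sample t test
#'
#' Two-tailed independent-samples Welch test (Satterthwaite degrees of
#' freedom). Thin wrapper over [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return List with `t`, `p`, and `df`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 observations per group")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("degenerate input: both groups have zero variance")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Jackknife test of whole-cohort vs accepted-subset means
#'
#' The whole cohort and its Goldberg-accepted subset are non-independent, so
#' the difference of their means is tested with a leave-one-out jackknife
#' over the full cohort: the statistic (mean of all minus mean of accepted)
#' is recomputed with each participant deleted, giving a jackknife SE and a
#' normal-approximation p-value. A statistic that is constant under deletion
#' yields a zero SE; the exact difference is then reported with p = 1 when
#' the difference is zero and p = NA otherwise.
#'
#' @param values per-participant values (e.g. reporting errors).
#' @param accepted logical vector: Goldberg acceptance per participant.
#' @param level confidence level, default 0.95.
#' @return List with `difference`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
paired_jackknife_test <- function(values, accepted, level = 0.95) {
  n <- length(values)
  if (length(accepted) != n) stop("values and accepted lengths differ")
  if (sum(accepted) <= 1) stop("accepted subset must have more than 1 member")
  stat <- function(v, a) mean(v) - mean(v[a])
  est <- stat(values, accepted)
  theta <- vapply(seq_len(n),
                  function(i) stat(values[-i], accepted[-i]), numeric(1))
  jackknife_from_loo(est, theta, level)[c("estimate", "se", "ci_low",
                                          "ci_high", "p_value")] |>
    stats::setNames(c("difference", "se", "ci_low", "ci_high", "p_value"))
}

#' Mean reporting-bias table
#'
#' For each nutrient, the mean and SD of the reporting error
#' (self-report minus biomarker) with a one-sample t test against zero,
#' computed on the whole cohort and on the Goldberg-accepted subset, plus
#' the jackknife test of the whole-vs-accepted mean difference.
#'
#' @param cohort cohort data frame.
#' @param params a [goldberg_params()] object.
#' @return Data frame with one row per nutrient x group.
#' @export
mean_bias_table <- function(cohort, params = goldberg_params()) {
  scr <- screen_cohort(cohort, params)
  acc <- !is.na(scr$results$accepted) & scr$results$accepted
  ok <- !is.na(scr$results$accepted)
  rows <- list()
  for (nu in c("ei", "si", "poi", "pri")) {
    cols <- nutrient_columns(nu)
    e <- cohort[[cols["sr"]]] - cohort[[cols["bio"]]]
    for (grp in c("all", "accepted")) {
      sel <- if (grp == "all") ok else acc
      tt <- one_sample_t(e[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = nu, group = grp, n = sum(sel), mean_bias = mean(e[sel]),
        sd_bias = stats::sd(e[sel]), se_bias = stats::sd(e[sel]) / sqrt(sum(sel)),
        t = tt$t, p = tt$p)
    }
    jk <- paired_jackknife_test(e[ok], acc[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      nutrient = nu, group = "all_minus_accepted", n = sum(ok),
      mean_bias = jk$difference, sd_bias = NA_real_, se_bias = jk$se,
      t = NA_real_, p = jk$p_value)
  }
  do.call(rbind, rows)
}

#' Accepted-vs-rejected group comparison table
#'
#' Per nutrient and per measure (reporting error, self-report, biomarker):
#' means, SDs, and standard errors in the Goldberg-accepted and rejected
#' groups, with Welch's t test of the group difference. Both SD and SE are
#' reported explicitly.
#'
#' @inheritParams mean_bias_table
#' @return Data frame with one row per nutrient x measure.
#' @export
group_comparison_table <- function(cohort, params = goldberg_params()) {
  scr <- screen_cohort(cohort, params)
  rows <- list()
  for (nu in c("ei", "si", "poi", "pri")) {
    cols <- nutrient_columns(nu)
    vals <- list(
      bias = function(d) d[[cols["sr"]]] - d[[cols["bio"]]],
      sr = function(d) d[[cols["sr"]]],
      bio = function(d) d[[cols["bio"]]])
    for (ms in names(vals)) {
      a <- vals[[ms]](scr$accepted); r <- vals[[ms]](scr$rejected)
      wt <- welch_t(a, r)
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = nu, measure = ms,
        n_accepted = length(a), n_rejected = length(r),
        mean_accepted = mean(a), sd_accepted = stats::sd(a),
        se_accepted = stats::sd(a) / sqrt(length(a)),
        mean_rejected = mean(r), sd_rejected = stats::sd(r),
        se_rejected = stats::sd(r) / sqrt(length(r)),
        t = wt$t, p = wt$p)
    }
  }
  do.call(rbind, rows)
}

#' Association-bias table over all nutrition-outcome pairs
#'
#' For each of the 24 nutrient-outcome pairs: the three regression slopes
#' (biomarker, self-report, Goldberg-accepted self-report), the percent bias
#' `b` and percent remaining bias `r`, and leave-one-out jackknife 95% CIs
#' for both. Goldberg classifications are computed once per participant and
#' held fixed across leave-one-out subsets (classification depends only on
#' the participant's own values, so re-screening each subset would change
#' nothing). Flags follow the usual reading: `significant_bias` when the b
#' CI excludes 0, `significant_remaining` when the r CI excludes 0, and
#' `significant_reduction` when the r CI lies within (-100, 100). Pairs
#' whose biomarker slope is below the denominator tolerance are flagged
#' unstable with undefined metrics.
#'
#' @inheritParams mean_bias_table
#' @param level confidence level for the jackknife CIs.
#' @param tol relative denominator tolerance passed to [percent_bias()].
#' @return Data frame with one row per pair.
#' @export
association_bias_table <- function(cohort, params = goldberg_params(),
                                   level = 0.95, tol = 1e-12) {
  scr <- screen_cohort(cohort, params)
  ok <- which(!is.na(scr$results$accepted))
  cohort <- cohort[ok, , drop = FALSE]
  acc <- scr$results$accepted[ok]
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- nrow(cohort)
  rows <- list()
  for (nu in c("ei", "si", "poi", "pri")) {
    x <- cohort[[nutrient_columns(nu)[["bio"]]]]
    xs <- cohort[[nutrient_columns(nu)[["sr"]]]]
    for (oc in c("bw", "wc", "hr", "sbp", "dbp", "vo2")) {
      y <- cohort[[outcome_columns(oc)]]
      beta_bio <- ols_fit(x, y)$beta_hat
      beta_sr <- ols_fit(xs, y)$beta_hat
      beta_g <- ols_fit(xs[acc], y[acc])$beta_hat
      unstable <- abs(beta_bio) <=
        tol * max(abs(beta_bio), abs(beta_sr), abs(beta_g), 1)
      if (unstable) {
        rows[[length(rows) + 1L]] <- data.frame(
          nutrient = nu, outcome = oc, beta_bio = beta_bio,
          beta_sr = beta_sr, beta_g = beta_g, b = NA_real_,
          b_lo = NA_real_, b_hi = NA_real_, r = NA_real_, r_lo = NA_real_,
          r_hi = NA_real_, significant_bias = NA,
          significant_remaining = NA, significant_reduction = NA,
          unstable = TRUE)
        next
      }
      b <- percent_bias(beta_sr, beta_bio, tol)
      r <- percent_remaining_bias(beta_g, beta_bio, tol)
      # leave-one-out slopes; deleting a rejected row leaves beta_g unchanged
      bio_i <- loo_slopes(x, y)
      sr_i <- loo_slopes(xs, y)
      g_i <- rep(beta_g, n)
      g_i[acc] <- loo_slopes(xs[acc], y[acc])
      b_i <- (sr_i - bio_i) / bio_i * 100
      r_i <- (g_i - bio_i) / bio_i * 100
      se_b <- sqrt((n - 1) / n * sum((b_i - mean(b_i))^2))
      se_r <- sqrt((n - 1) / n * sum((r_i - mean(r_i))^2))
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = nu, outcome = oc, beta_bio = beta_bio,
        beta_sr = beta_sr, beta_g = beta_g,
        b = b, b_lo = b - z * se_b, b_hi = b + z * se_b,
        r = r, r_lo = r - z * se_r, r_hi = r + z * se_r,
        significant_bias = (b - z * se_b > 0) | (b + z * se_b < 0),
        significant_remaining = (r - z * se_r > 0) | (r + z * se_r < 0),
        significant_reduction = (r - z * se_r > -100) & (r + z * se_r < 100),
        unstable = FALSE)
    }
  }
  do.call(rbind, rows)
}
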