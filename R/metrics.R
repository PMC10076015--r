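#' Percent bias of the self-report association estimate
#'
#' `b = (beta_sr - beta_bio) / beta_bio * 100`. Attenuation of either a
#' positive or a negative biomarker slope gives negative `b`.
#'
#' @param beta_sr slope estimated from self-reported intake.
#' @param beta_bio slope estimated from biomarker intake.
#' @param tol relative tolerance below which the denominator is treated as
#'   unstable.
#' @return Percent bias.
#' @export
percent_bias <- function(beta_sr, beta_bio, tol = 1e-12) {
  scale <- max(abs(beta_sr), abs(beta_bio), 1)
  if (!is.finite(beta_bio) || abs(beta_bio) <= tol * scale)
    stop("unstable denominator: |beta_bio| below tolerance")
  (beta_sr - beta_bio) / beta_bio * 100
}

#' Percent remaining bias after Goldberg screening
#'
#' `r = (beta_g - beta_bio) / beta_bio * 100`, where `beta_g` is the slope
#' estimated from the Goldberg-accepted self-reports.
#'
#' @param beta_g slope estimated from accepted self-reports.
#' @inheritParams percent_bias
#' @return Percent remaining bias.
#' @export
percent_remaining_bias <- function(beta_g, beta_bio, tol = 1e-12) {
  percent_bias(beta_g, beta_bio, tol)
}

#' Jackknife (leave-one-out) confidence interval of a statistic
#'
#' Computes the statistic on every leave-one-out subset, the jackknife
#' standard error `sqrt((n - 1)/n * sum((theta_i - mean(theta_i))^2))`, and
#' a normal-approximation interval around the full-sample estimate.
#'
#' @param data a vector or data frame (rows are resampling units).
#' @param statistic function of `data` returning a single number.
#' @param level confidence level, default 0.95.
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, and the vector
#'   of leave-one-out `replicates`.
#' @export
jackknife_ci <- function(data, statistic, level = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 3) stop("need at least 3 observations")
  drop_i <- if (is.data.frame(data)) {
    function(i) data[-i, , drop = FALSE]
  } else {
    function(i) data[-i]
  }
  est <- statistic(data)
  theta <- vapply(seq_len(n), function(i) {
    tryCatch(statistic(drop_i(i)),
             error = function(e) stop("leave-one-out statistic failed at index ",
                                      i, ": ", conditionMessage(e)))
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, ci_low = est - z * se, ci_high = est + z * se,
       replicates = theta)
}

# CI and p-value from precomputed leave-one-out replicates (normal
# approximation around the full-sample estimate).
jackknife_from_loo <- function(estimate, theta, level = 0.95) {
  n <- length(theta)
  se <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) { if (estimate == 0) 1 else NA_real_ }
       else 2 * stats::pnorm(-abs(estimate) / se)
  list(estimate = estimate, se = se, ci_low = estimate - z * se,
       ci_high = estimate + z * se, p_value = p)
}

#' Summarise estimator performance across simulation replicates
#'
#' Bias is `mean(beta_hat) - beta1`. MSE follows the population-variance
#' convention, `(1/n) sum((beta_hat_i - mean)^2) + (mean - beta1)^2`, so it
#' equals `(1/n) sum((beta_hat_i - beta1)^2)` algebraically. Coverage is the
#' fraction of replicates whose interval strictly contains `beta1`.
#' Replicates with missing estimates (flagged Goldberg fits) are excluded
#' and counted.
#'
#' @param beta_hat per-replicate slope estimates.
#' @param ci_low,ci_high per-replicate 95% bounds.
#' @param beta1 the true slope (source-cohort point estimate).
#' @return One-row data frame with `bias`, `mse`, `coverage`, `beta1`,
#'   `n_replicates_used`.
#' @export
summarize_performance <- function(beta_hat, ci_low, ci_high, beta1) {
  keep <- !is.na(beta_hat)
  beta_hat <- beta_hat[keep]; ci_low <- ci_low[keep]; ci_high <- ci_high[keep]
  n <- length(beta_hat)
  if (n < 2) stop("need at least 2 usable replicates")
  m <- mean(beta_hat)
  bias <- m - beta1
  mse <- mean((beta_hat - m)^2) + bias^2
  coverage <- mean(ci_low < beta1 & beta1 < ci_high)
  data.frame(bias = bias, mse = mse, coverage = coverage, beta1 = beta1,
             n_replicates_used = n)
}

#' Performance table of a simulation run
#'
#' Applies [summarize_performance()] to every nutrient x outcome x estimator
#' cell of a [run_simulation()] result.
#'
#' @param sim a `goldberg_sim` object.
#' @return Data frame with one row per cell: `nutrient`, `outcome`,
#'   `estimator`, `bias`, `mse`, `coverage`, `beta1`, `n_replicates_used`.
#' @export
summarize_simulation <- function(sim) {
  stopifnot(inherits(sim, "goldberg_sim"))
  res <- sim$results
  cells <- unique(res[, c("nutrient", "outcome", "estimator")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sel <- res$nutrient == cell$nutrient & res$outcome == cell$outcome &
      res$estimator == cell$estimator
    b1 <- sim$beta1$beta1[sim$beta1$nutrient == cell$nutrient &
                            sim$beta1$outcome == cell$outcome]
    cbind(cell,
          summarize_performance(res$beta_hat[sel], res$ci_low[sel],
                                res$ci_high[sel], b1),
          row.names = NULL)
  })
  do.call(rbind, rows)
}
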