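#' Simple linear regression with a t-based confidence interval
#'
#' Closed-form bivariate OLS used throughout the simulation engine (it is
#' fitted hundreds of thousands of times per run). Agreement with
#' `lm()`/`confint()` is asserted in the test suite.
#'
#' @param x predictor.
#' @param y response, same length.
#' @param level confidence level, default 0.95.
#' @return A list with `intercept`, `beta_hat`, `se`, `ci_low`, `ci_high`,
#'   `sigma` (residual SD), and `n_used`.
#' @export
ols_fit <- function(x, y, level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3) stop("need at least 3 observations")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx <= 0) stop("fit failure: predictor has zero variance")
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  list(intercept = intercept, beta_hat = slope, se = se,
       ci_low = slope - tq * se, ci_high = slope + tq * se,
       sigma = sqrt(s2), n_used = n)
}

#' Leave-one-out regression slopes
#'
#' Returns the n slopes of the bivariate regression of `y` on `x` with each
#' observation deleted in turn, computed in O(n) from the sufficient
#' statistics. Used by the jackknife over association-bias metrics.
#'
#' @param x predictor.
#' @param y response, same length (at least 4 observations so every
#'   leave-one-out fit is defined).
#' @return Numeric vector of length `n`.
#' @export
loo_slopes <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4) stop("need at least 4 observations")
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  m <- n - 1
  sx_i <- sx - x; sy_i <- sy - y
  num <- m * (sxy - x * y) - sx_i * sy_i
  den <- m * (sxx - x^2) - sx_i^2
  if (any(den <= 0))
    stop("fit failure in a leave-one-out subset: predictor degenerate")
  num / den
}
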