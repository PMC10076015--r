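# Calibration of generator truths from printed cohort summary statistics.
#
# The reporting error is e = mu(p(NI_BIO)) + N(0, sigma^2) with p the
# (approximately uniform) empirical percentile of the biomarker intake.
# Writing mu on the shifted-Legendre basis L_j(p) (orthogonal on U(0,1),
# Var(L_j(P)) = 1/(2j+1)) makes the three calibration targets separable:
#   mean(e)        = c_0                         (L_0 = 1)
#   Var(e)         = sum_j c_j^2 / (2j+1) + sigma^2
#   Cov(e, NI_BIO) = sd_bio * sum_j c_j * kappa_j,
# where kappa_j = E[L_j(Phi(Z)) Z] for standard normal Z (zero for even j).

# Shifted Legendre polynomials on [0,1], raw-power coefficients (constant
# term first), rows j = 0..5.
.shifted_legendre <- rbind(
  c(1, 0, 0, 0, 0, 0),
  c(-1, 2, 0, 0, 0, 0),
  c(1, -6, 6, 0, 0, 0),
  c(-1, 12, -30, 20, 0, 0),
  c(1, -20, 90, -140, 70, 0),
  c(-1, 30, -210, 560, -630, 252))

# kappa_j = E[L_j(Phi(Z)) * Z], j = 1..5; kappa_1 = 1/sqrt(pi) exactly, the
# others evaluated by dense Gauss quadrature (verified in the test suite
# against an independent grid integration).
.legendre_kappa <- c(0.564189583547756, 0, 0.0691706120073672, 0,
                     0.0246331690572482)

#' Correlation of self-report with biomarker implied by printed SDs
#'
#' From the variance identity
#' `Var(SR - BIO) = Var(SR) + Var(BIO) - 2 Cov(SR, BIO)`, the correlation of
#' self-reported with biomarker intake is recovered from the three printed
#' standard deviations.
#'
#' @param sd_sr SD of self-reported intake.
#' @param sd_bio SD of biomarker intake.
#' @param sd_bias SD of the reporting error (SR minus BIO).
#' @return The implied correlation, strictly inside (-1, 1).
#' @examples
#' derive_sr_bio_correlation(783.4, 492.8, 811.0) # about 0.2575 for energy
#' @export
derive_sr_bio_correlation <- function(sd_sr, sd_bio, sd_bias) {
  if (sd_sr <= 0 || sd_bio <= 0 || sd_bias < 0)
    stop("sd_sr and sd_bio must be positive; sd_bias non-negative")
  rho <- (sd_sr^2 + sd_bio^2 - sd_bias^2) / (2 * sd_sr * sd_bio)
  if (abs(rho) >= 1)
    stop("inconsistent calibration: implied |correlation| >= 1 (", round(rho, 4), ")")
  rho
}

#' Calibrate a linear mean-error function from summary targets
#'
#' Solves for `(m_0, m_1, sigma)` of a linear mean-error model
#' `e = m_0 + m_1 p + N(0, sigma^2)` so that, with percentiles uniform on
#' (0, 1) and a normal biomarker marginal, the reporting error reproduces a
#' target mean, SD, and correlation with the biomarker intake. Uses the
#' closed form `Cov(P, BIO) = sd_bio / (2 sqrt(pi))` for normal BIO.
#'
#' @param target_bias_mean target mean reporting error.
#' @param target_bias_sd target SD of the reporting error.
#' @param target_error_bio_corr target correlation of error with biomarker
#'   intake, strictly inside (-1, 1).
#' @return List with `coefficients = c(m0, m1)` and `sigma`.
#' @export
calibrate_linear_mu <- function(target_bias_mean, target_bias_sd,
                                target_error_bio_corr) {
  if (abs(target_error_bio_corr) >= 1)
    stop("inconsistent calibration: |target correlation| must be < 1")
  if (target_bias_sd < 0) stop("target_bias_sd must be non-negative")
  # Cov(e, BIO) = m1 * Cov(P, BIO) = m1 * sd_bio / (2 sqrt(pi));
  # corr * sd_e * sd_bio = m1 * sd_bio / (2 sqrt(pi))
  m1 <- 2 * sqrt(pi) * target_error_bio_corr * target_bias_sd
  s2 <- target_bias_sd^2 - m1^2 / 12
  if (s2 < 0)
    stop("inconsistent calibration: no feasible (m1, sigma); ",
         "target correlation too strong for the target SD")
  m0 <- target_bias_mean - m1 / 2
  list(coefficients = c(m0 = m0, m1 = m1), sigma = sqrt(s2))
}

#' Calibrate a polynomial mean-error function of a designated order
#'
#' Generalises [calibrate_linear_mu()] to odd polynomial orders 1, 3, 5 by
#' assigning fixed shares of the total error variance to the cubic and
#' quintic shifted-Legendre components (signed to reinforce a decreasing
#' trend when the target correlation is negative), then solving the linear
#' component from the covariance target and the noise SD from the variance
#' budget.
#'
#' @inheritParams calibrate_linear_mu
#' @param order polynomial order of the mean-error function (1, 3, or 5).
#' @param shares named numeric vector of error-variance shares for the
#'   higher-order components, e.g. `c("3" = 0.10)`; defaults by order:
#'   none for order 1, 10% cubic for order 3, 5% quintic + 2% cubic for
#'   order 5.
#' @return List with `coefficients = c(m_0, ..., m_K)` on the raw power
#'   basis, `sigma`, and `legendre` (the basis weights).
#' @export
calibrate_mu <- function(target_bias_mean, target_bias_sd,
                         target_error_bio_corr, order = 1, shares = NULL) {
  if (!order %in% c(1, 3, 5)) stop("order must be 1, 3, or 5")
  if (abs(target_error_bio_corr) >= 1)
    stop("inconsistent calibration: |target correlation| must be < 1")
  if (is.null(shares)) {
    shares <- switch(as.character(order),
                     "1" = numeric(0),
                     "3" = c("3" = 0.10),
                     "5" = c("3" = 0.02, "5" = 0.05))
  }
  v_e <- target_bias_sd^2
  sgn <- if (target_error_bio_corr < 0) -1 else 1
  c_leg <- numeric(6) # weights for L_0 .. L_5
  c_leg[1] <- target_bias_mean
  for (j in as.integer(names(shares))) {
    c_leg[j + 1] <- sgn * sqrt(shares[[as.character(j)]] * v_e * (2 * j + 1))
  }
  # covariance target: sum_j c_j kappa_j = corr * sd_e
  resid_cov <- target_error_bio_corr * target_bias_sd -
    sum(c_leg[2:6] * .legendre_kappa)
  c_leg[2] <- c_leg[2] + resid_cov / .legendre_kappa[1]
  var_mu <- sum(c_leg[2:6]^2 / (2 * (1:5) + 1))
  s2 <- v_e - var_mu
  if (s2 < 0)
    stop("inconsistent calibration: mean-error variance exceeds the target ",
         "error variance; reduce shares or the correlation target")
  cf <- drop(c_leg %*% .shifted_legendre)[seq_len(order + 1)]
  names(cf) <- paste0("m", seq_along(cf) - 1L)
  list(coefficients = cf, sigma = sqrt(s2), legendre = c_leg)
}
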