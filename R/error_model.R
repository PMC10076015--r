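#' Percentile reference distribution
#'
#' Stores the sorted biomarker intake values of a reference cohort and maps
#' arbitrary intake values to empirical percentiles under the Hazen
#' convention, `p = (rank - 0.5) / n`. The reference is kept fixed (the full
#' source cohort), so a mean-error function fitted against it is always
#' evaluated on the scale it was fitted on.
#'
#' @param values numeric vector of reference intakes; non-empty, finite.
#' @return An object of class `percentile_ref`.
#' @export
percentile_ref <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("reference values must be non-empty and finite")
  structure(list(values = sort(values), n = length(values)),
            class = "percentile_ref")
}

#' Empirical percentile of a value
#'
#' Hazen plotting position for in-sample values, linear interpolation
#' between them, and clamping of out-of-range values to
#' `[0.5/n, 1 - 0.5/n]`. Monotone non-decreasing in `x`.
#'
#' @param ref a [percentile_ref()] object.
#' @param x values to convert (vectorised).
#' @return Percentiles as fractions in `[0, 1]`.
#' @examples
#' r <- percentile_ref(c(10, 20, 30))
#' empirical_percentile(r, 20) # 0.5
#' @export
empirical_percentile <- function(ref, x) {
  if (!inherits(ref, "percentile_ref")) stop("ref must be a percentile_ref")
  n <- ref$n
  pp <- (seq_len(n) - 0.5) / n
  if (n == 1) return(rep(0.5, length(x)))
  stats::approx(ref$values, pp, xout = x, rule = 2, ties = mean)$y
}

#' Mean reporting-error function
#'
#' Evaluates the polynomial mean-error function
#' `mu(p) = sum_k m_k p^k` at percentile `p`.
#'
#' @param model an `error_model` object or a bare numeric coefficient vector
#'   `c(m_0, ..., m_K)`.
#' @param p percentile fractions in `[0, 1]` (vectorised).
#' @return Mean error in the nutrient's units.
#' @export
mean_error <- function(model, p) {
  coefs <- if (inherits(model, "error_model")) model$coefficients
           else as.numeric(model)
  if (length(coefs) == 0) stop("no coefficients")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  # Horner evaluation
  out <- rep(coefs[length(coefs)], length(p))
  for (k in rev(seq_len(length(coefs) - 1L))) out <- out * p + coefs[k]
  out
}

#' Least-squares fit of the polynomial mean-error function
#'
#' @param percentiles fractions in `[0, 1]`.
#' @param errors reporting errors (self-report minus biomarker), same length.
#' @param order polynomial order K.
#' @return Coefficient vector `c(m_0, ..., m_K)`.
#' @export
fit_mean_error <- function(percentiles, errors, order) {
  n <- length(percentiles)
  if (length(errors) != n) stop("percentiles and errors lengths differ")
  if (n < order + 1) stop("need at least order + 1 observations")
  X <- stats::poly(percentiles, degree = order, raw = TRUE, simple = TRUE)
  fit <- stats::lm.fit(cbind(1, X), errors)
  if (fit$rank < order + 1)
    stop("rank-deficient design: cannot fit polynomial of order ", order)
  cf <- unname(fit$coefficients)
  names(cf) <- paste0("m", 0:order)
  cf
}

#' Select the polynomial order by k-fold cross-validation
#'
#' Assigns observations to near-equal random folds (drawn from the current
#' RNG stream), computes the out-of-fold mean squared error of the
#' polynomial fit for each candidate order, and returns the order with the
#' smallest CV-MSE. Orders tying to within `1e-10` relative are resolved in
#' favour of the smaller order (parsimony).
#'
#' @param percentiles,errors as in [fit_mean_error()].
#' @param k_range candidate orders, by default `1:5`.
#' @param folds number of folds, default 10.
#' @return The selected order (integer), with attribute `cv_mse` giving the
#'   per-candidate CV mean squared errors.
#' @export
select_order_cv <- function(percentiles, errors, k_range = 1:5, folds = 10) {
  n <- length(percentiles)
  if (length(errors) != n) stop("percentiles and errors lengths differ")
  if (n < folds) stop("need at least as many observations as folds")
  fold <- sample(rep_len(seq_len(folds), n))
  cv_mse <- vapply(k_range, function(k) {
    sse <- 0
    for (f in seq_len(folds)) {
      test <- fold == f
      cf <- fit_mean_error(percentiles[!test], errors[!test], k)
      sse <- sse + sum((errors[test] - mean_error(cf, percentiles[test]))^2)
    }
    sse / n
  }, numeric(1))
  best <- min(cv_mse)
  ok <- which(cv_mse <= best * (1 + 1e-10) + 1e-300)
  sel <- as.integer(k_range[min(ok)])
  attr(sel, "cv_mse") <- stats::setNames(cv_mse, paste0("K", k_range))
  sel
}

#' Residual standard deviation of the error model
#'
#' SD of the residuals `e - mu(p)` with degrees-of-freedom correction
#' `n - (K + 1)`.
#'
#' @param percentiles,errors as in [fit_mean_error()].
#' @param coefficients fitted coefficient vector `c(m_0, ..., m_K)`.
#' @return Estimated constant error SD.
#' @export
estimate_sigma <- function(percentiles, errors, coefficients) {
  n <- length(errors)
  df <- n - length(coefficients)
  if (df < 1) stop("need more observations than coefficients")
  res <- errors - mean_error(coefficients, percentiles)
  sqrt(sum(res^2) / df)
}

#' Goldfeld-Quandt test for heteroskedasticity
#'
#' Orders the errors by `ordering`, discards the central
#' `round(n * middle_frac)` observations (round half up; 303 observations at
#' 20% discard the center 61), and compares the variances of the low and
#' high groups about their own means. The statistic is the ratio of the
#' larger to the smaller group variance; the p-value is two-sided from the F
#' distribution.
#'
#' @param errors numeric vector of reporting errors.
#' @param ordering numeric vector (same length) by which to sort, typically
#'   the biomarker intake.
#' @param middle_frac fraction of central observations to discard, default 0.2.
#' @return A list with `statistic` (F), `p_value`, `n_discarded`, and the two
#'   group sizes.
#' @export
goldfeld_quandt <- function(errors, ordering, middle_frac = 0.2) {
  n <- length(errors)
  if (length(ordering) != n) stop("errors and ordering lengths differ")
  if (middle_frac < 0 || middle_frac >= 1) stop("middle_frac must be in [0, 1)")
  n_disc <- as.integer(floor(n * middle_frac + 0.5)) # round half up
  n_keep <- n - n_disc
  n_low <- n_keep %/% 2L
  n_high <- n_keep - n_low
  if (n_low < 2 || n_high < 2)
    stop("groups too small after discarding the central band")
  e <- errors[order(ordering)]
  low <- e[seq_len(n_low)]
  high <- e[seq.int(n - n_high + 1L, n)]
  v_low <- stats::var(low)
  v_high <- stats::var(high)
  if (v_high >= v_low) {
    f <- v_high / v_low; df1 <- n_high - 1L; df2 <- n_low - 1L
  } else {
    f <- v_low / v_high; df1 <- n_low - 1L; df2 <- n_high - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(statistic = f, p_value = p, n_discarded = n_disc,
       n_low = n_low, n_high = n_high)
}

#' Fit the full reporting-error model for one nutrient
#'
#' Computes per-participant reporting errors `NI_SR - NI_BIO`, converts the
#' biomarker intakes to empirical percentiles against the full cohort,
#' selects the polynomial order by 10-fold cross-validation, fits the mean
#' error function, and estimates the constant error SD.
#'
#' @param cohort data frame with the standard intake columns (see
#'   [cohort_columns()]).
#' @param nutrient one of `"ei"`, `"si"`, `"poi"`, `"pri"`.
#' @param k_range candidate polynomial orders.
#' @param folds number of CV folds.
#' @return An object of class `error_model`: list with `nutrient`,
#'   `coefficients`, `order`, `sigma`, `reference` (a [percentile_ref()]),
#'   and `cv_mse`.
#' @export
fit_error_model <- function(cohort, nutrient, k_range = 1:5, folds = 10) {
  cols <- nutrient_columns(nutrient)
  sr <- cohort[[cols["sr"]]]
  bio <- cohort[[cols["bio"]]]
  if (is.null(sr) || is.null(bio))
    stop("cohort lacks columns ", cols["sr"], " / ", cols["bio"])
  keep <- !is.na(sr) & !is.na(bio)
  sr <- sr[keep]; bio <- bio[keep]
  e <- sr - bio
  ref <- percentile_ref(bio)
  p <- empirical_percentile(ref, bio)
  k <- select_order_cv(p, e, k_range = k_range, folds = folds)
  cf <- fit_mean_error(p, e, k)
  structure(list(nutrient = nutrient, coefficients = cf,
                 order = as.integer(k), sigma = estimate_sigma(p, e, cf),
                 reference = ref, cv_mse = attr(k, "cv_mse")),
            class = "error_model")
}

#' Construct an error model from known components
#'
#' Useful for building generator truths and constructed scenarios without
#' fitting.
#'
#' @param coefficients polynomial coefficients `c(m_0, ..., m_K)`.
#' @param sigma constant error SD, non-negative.
#' @param reference a [percentile_ref()] object.
#' @param nutrient optional nutrient tag.
#' @return An `error_model` object.
#' @export
error_model <- function(coefficients, sigma, reference, nutrient = NA_character_) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!inherits(reference, "percentile_ref"))
    stop("reference must be a percentile_ref")
  structure(list(nutrient = nutrient,
                 coefficients = as.numeric(coefficients),
                 order = length(coefficients) - 1L, sigma = sigma,
                 reference = reference, cv_mse = NULL),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Reporting-error model%s: order K = %d, sigma = %.4g\n",
              if (is.na(x$nutrient)) "" else paste0(" (", x$nutrient, ")"),
              x$order, x$sigma))
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients),
                               collapse = ", "), "\n")
  invisible(x)
}

# Column lookup for the four nutrients in the standard cohort schema.
nutrient_columns <- function(nutrient) {
  tab <- list(ei  = c(sr = "ei_sr_kcal",  bio = "ei_bio_kcal"),
              si  = c(sr = "si_sr_mg",    bio = "si_bio_mg"),
              poi = c(sr = "poi_sr_mg",   bio = "poi_bio_mg"),
              pri = c(sr = "pri_sr_g",    bio = "pri_bio_g"))
  if (!nutrient %in% names(tab))
    stop("unknown nutrient: ", nutrient,
         " (expected one of ei, si, poi, pri)")
  tab[[nutrient]]
}
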