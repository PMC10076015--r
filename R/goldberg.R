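#' Goldberg cutoff parameters
#'
#' Bundle of the variation components entering the Goldberg plausibility
#' interval for the ratio of self-reported energy intake to predicted energy
#' expenditure. Defaults follow the values conventionally used for a 7-day
#' dietary assessment: PAL 1.75, within-subject CV of reported energy intake
#' 23%, within-subject CV of BMR 8.5%, total CV of PAL 15%.
#'
#' @param pal physical activity level (dimensionless multiplier on BMR).
#' @param cv_ei within-subject coefficient of variation of reported energy
#'   intake, percent.
#' @param cv_b within-subject coefficient of variation of BMR, percent.
#' @param cv_p total coefficient of variation of PAL, percent.
#' @param d number of days of diet assessment.
#' @return An object of class `goldberg_params`.
#' @examples
#' goldberg_params()
#' goldberg_params(pal = 1.55, d = 1)
#' @export
goldberg_params <- function(pal = 1.75, cv_ei = 23, cv_b = 8.5, cv_p = 15,
                            d = 7) {
  vals <- c(pal = pal, cv_ei = cv_ei, cv_b = cv_b, cv_p = cv_p, d = d)
  if (any(!is.finite(vals)) || pal <= 0 || d <= 0 ||
      any(c(cv_ei, cv_b, cv_p) < 0))
    stop("pal and d must be strictly positive; CVs must be non-negative")
  structure(as.list(vals), class = "goldberg_params")
}

#' @export
print.goldberg_params <- function(x, ...) {
  cat("Goldberg cutoff parameters\n")
  cat(sprintf("  PAL = %g, CV_wEI = %g%%, CV_wB = %g%%, CV_tP = %g%%, d = %g\n",
              x$pal, x$cv_ei, x$cv_b, x$cv_p, x$d))
  s <- cutoff_s(x)
  bd <- cutoff_bounds(s)
  cat(sprintf("  S = %.3f%%  ->  plausibility bounds (%.4f, %.4f)\n",
              s, bd[1], bd[2]))
  invisible(x)
}

#' Predict basal metabolic rate from fat-free mass
#'
#' BMR (kcal/day) is predicted linearly from fat-free mass:
#' `BMR = 370 + 21.6 * FFM`.
#'
#' @param ffm fat-free mass in kg; strictly positive.
#' @return Predicted BMR in kcal/day.
#' @examples
#' predict_bmr(50) # 1450
#' @export
predict_bmr <- function(ffm) {
  if (length(ffm) == 0 || any(is.na(ffm)) || any(!is.finite(ffm)) ||
      any(ffm <= 0))
    stop("ffm must be strictly positive and non-missing")
  370 + 21.6 * ffm
}

#' Predict energy expenditure from BMR and physical activity level
#'
#' @param bmr basal metabolic rate, kcal/day; strictly positive.
#' @param pal physical activity level; strictly positive.
#' @return Predicted energy expenditure `pal * bmr`, kcal/day.
#' @export
predict_ee <- function(bmr, pal) {
  if (any(is.na(bmr)) || any(bmr <= 0)) stop("bmr must be strictly positive")
  if (any(is.na(pal)) || any(pal <= 0)) stop("pal must be strictly positive")
  pal * bmr
}

#' Combined variation coefficient S of the Goldberg interval
#'
#' `S = sqrt(cv_ei^2 / d + cv_b^2 + cv_p^2)`, in percent. S aggregates the
#' within-subject variation of reported intake (shrunk by the number of
#' assessment days), the within-subject variation of BMR, and the total
#' variation of PAL.
#'
#' @param params a [goldberg_params()] object.
#' @return S in percent.
#' @examples
#' cutoff_s(goldberg_params()) # about 19.31
#' @export
cutoff_s <- function(params) {
  stopifnot(inherits(params, "goldberg_params"))
  sqrt(params$cv_ei^2 / params$d + params$cv_b^2 + params$cv_p^2)
}

#' Plausibility bounds of the intake:expenditure ratio
#'
#' The reported-intake to predicted-expenditure ratio is deemed plausible
#' inside `(exp(-2 S / 100), exp(+2 S / 100))`. The two bounds multiply to 1.
#'
#' @param s combined variation coefficient in percent, non-negative.
#' @return Numeric vector `c(lower, upper)`.
#' @export
cutoff_bounds <- function(s) {
  if (any(is.na(s)) || any(s < 0)) stop("s must be non-negative")
  c(lower = exp(-2 * s / 100), upper = exp(2 * s / 100))
}

#' Classify participants with the Goldberg cutoffs
#'
#' Composes BMR prediction, expenditure prediction, and the plausibility
#' interval. A participant is accepted when the ratio of self-reported energy
#' intake to predicted expenditure lies strictly between the bounds; ratios
#' exactly on a bound are rejected (literal reading of the strict
#' inequalities).
#'
#' @param ei_sr self-reported energy intake, kcal/day; non-negative. May be a
#'   vector (classified element-wise against `ffm` of the same length).
#' @param ffm fat-free mass, kg; strictly positive.
#' @param params a [goldberg_params()] object.
#' @return A data frame with one row per participant and columns `bmr`, `ee`,
#'   `ratio`, `s`, `lower`, `upper`, `accepted`.
#' @examples
#' goldberg_classify(2048, 48.9, goldberg_params())
#' @export
goldberg_classify <- function(ei_sr, ffm, params = goldberg_params()) {
  if (length(ei_sr) != length(ffm))
    stop("ei_sr and ffm must have equal length")
  if (any(is.na(ei_sr)) || any(is.na(ffm)))
    stop("cannot classify: missing ei_sr or ffm")
  if (any(ei_sr < 0)) stop("ei_sr must be non-negative")
  bmr <- predict_bmr(ffm)
  ee <- predict_ee(bmr, params$pal)
  s <- cutoff_s(params)
  bd <- cutoff_bounds(s)
  ratio <- ei_sr / ee
  data.frame(bmr = bmr, ee = ee, ratio = ratio, s = s,
             lower = bd[["lower"]], upper = bd[["upper"]],
             accepted = ratio > bd[["lower"]] & ratio < bd[["upper"]])
}

#' Screen a cohort with the Goldberg cutoffs
#'
#' Applies [goldberg_classify()] to every participant with complete
#' `ei_sr_kcal` and `ffm_kg`. Classification uses energy intake only; callers
#' propagate the resulting exclusions to all nutrients. Participants missing
#' either input are dropped from both partitions with a message (mirroring
#' exclusion of participants lacking the inputs needed to apply the rule).
#' Each participant's classification depends only on that participant's own
#' values, so the partition is invariant to who else is in the cohort.
#'
#' @param cohort data frame with columns `ei_sr_kcal` and `ffm_kg` (other
#'   columns are carried along).
#' @param params a [goldberg_params()] object.
#' @return A list with elements `accepted` and `rejected` (disjoint,
#'   exhaustive row subsets of the complete-case cohort), `results` (the
#'   per-participant classification table, `NA` rows for participants with
#'   missing inputs), and `n_dropped` (count of participants dropped for
#'   missing inputs).
#' @export
screen_cohort <- function(cohort, params = goldberg_params()) {
  stopifnot(is.data.frame(cohort))
  req <- c("ei_sr_kcal", "ffm_kg")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0)
    stop("cohort lacks required columns: ", paste(miss, collapse = ", "))
  if (nrow(cohort) == 0) {
    warning("empty cohort: returning empty partition")
    res <- data.frame(bmr = numeric(0), ee = numeric(0), ratio = numeric(0),
                      s = numeric(0), lower = numeric(0), upper = numeric(0),
                      accepted = logical(0))
    return(list(accepted = cohort, rejected = cohort, results = res,
                n_dropped = 0L))
  }
  complete <- !is.na(cohort$ei_sr_kcal) & !is.na(cohort$ffm_kg)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " participant(s) dropped: missing ei_sr_kcal or ffm_kg")
  results <- data.frame(bmr = rep(NA_real_, nrow(cohort)), ee = NA_real_,
                        ratio = NA_real_, s = NA_real_, lower = NA_real_,
                        upper = NA_real_, accepted = NA)
  if (any(complete)) {
    results[complete, ] <- goldberg_classify(cohort$ei_sr_kcal[complete],
                                             cohort$ffm_kg[complete], params)
  }
  keep <- which(complete)
  acc <- keep[results$accepted[keep]]
  rej <- keep[!results$accepted[keep]]
  list(accepted = cohort[acc, , drop = FALSE],
       rejected = cohort[rej, , drop = FALSE],
       results = results,
       n_dropped = n_dropped)
}
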