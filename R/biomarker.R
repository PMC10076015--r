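#' Biomarker conversion constants
#'
#' Urinary excretion fractions (0.81 of consumed nitrogen, 0.80 of
#' potassium, 0.86 of sodium appear in 24-hr urine), the nitrogen share of
#' protein (0.16), and the energy density of body-weight change
#' (2380 kcal/kg).
#'
#' @return Named list of constants.
#' @export
biomarker_constants <- function() {
  list(excretion_nitrogen = 0.81, excretion_potassium = 0.80,
       excretion_sodium = 0.86, nitrogen_share_of_protein = 0.16,
       energy_density_kcal_per_kg = 2380)
}

#' Convert a 24-hr urinary amount to daily intake
#'
#' Divides the urinary amount by the excretion fraction of the nutrient.
#'
#' @param urinary_amount amount recovered in 24-hr urine (nutrient units/day).
#' @param excretion_fraction fraction of intake excreted, in (0, 1].
#' @return Estimated daily intake in the same units.
#' @examples
#' urine_to_intake(3453.6, 0.86) # sodium, about 4016 mg/day
#' @export
urine_to_intake <- function(urinary_amount, excretion_fraction) {
  if (any(urinary_amount < 0)) stop("urinary_amount must be non-negative")
  if (any(excretion_fraction <= 0) || any(excretion_fraction > 1))
    stop("excretion_fraction must lie in (0, 1]")
  urinary_amount / excretion_fraction
}

#' Convert nitrogen intake to protein intake
#'
#' Assumes 16% of protein mass is nitrogen.
#'
#' @param nitrogen_intake g/day, non-negative.
#' @return Protein intake, g/day.
#' @examples
#' protein_from_nitrogen(16) # 100 g/day
#' @export
protein_from_nitrogen <- function(nitrogen_intake) {
  if (any(nitrogen_intake < 0)) stop("nitrogen_intake must be non-negative")
  nitrogen_intake / biomarker_constants()$nitrogen_share_of_protein
}

#' Energy intake from energy balance
#'
#' Biomarker energy intake is total energy expenditure plus the daily change
#' in energy stores, the latter converted from daily weight change at the
#' energy density of body weight. The expenditure value itself (e.g. from
#' doubly labeled water) is taken as an input number.
#'
#' @param tee total energy expenditure, kcal/day; strictly positive.
#' @param daily_weight_change kg/day (negative when losing weight).
#' @param density energy density of weight change, kcal/kg.
#' @return Estimated energy intake, kcal/day.
#' @examples
#' ei_from_energy_balance(2400, 0.01) # 2423.8
#' @export
ei_from_energy_balance <- function(tee, daily_weight_change,
                                   density = biomarker_constants()$energy_density_kcal_per_kg) {
  if (any(tee <= 0)) stop("tee must be strictly positive")
  tee + density * daily_weight_change
}
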