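# goldbergsim

Does screening out "implausible" self-reported energy intake with the
Goldberg cutoffs remove reporting bias from nutrition-health association
estimates? This package implements the complete analysis needed to answer
that question for energy, sodium, potassium, and protein intake against six
health outcomes (body weight, waist circumference, post-test heart rate,
resting systolic/diastolic blood pressure, VO2 max): the screening rule, a
percentile-based reporting-error model, a plasmode-style Monte Carlo
simulation engine, and the performance metrics used to judge the screen.
A synthetic cohort generator calibrated to published summary statistics
stands in for the access-restricted empirical data, so the whole pipeline
runs out of the box.

It is aimed at nutrition epidemiologists and biostatisticians who work with
paired self-report/biomarker intake data (ASA24 against doubly-labeled
water and 24-hr urine biomarkers) or who design simulation studies of
measurement-error corrections.

## The method in brief

**Goldberg cutoffs.** Basal metabolic rate is predicted from fat-free mass,
`BMR = 370 + 21.6 FFM` (kcal/day), energy expenditure as `EE = PAL * BMR`
with PAL = 1.75, and a participant is accepted when

```
exp(-2S/100) < EI_SR : EE < exp(+2S/100),
S = sqrt(CV_wEI^2/d + CV_wB^2 + CV_tP^2)
```

with CV_wEI = 23%, CV_wB = 8.5%, CV_tP = 15%, d = 7, giving S ≈ 19.31% and
bounds (0.680, 1.471). Screening uses energy only; exclusions propagate to
all nutrients.

**Reporting-error model.** The error `e = NI_SR − NI_BIO` is Gaussian with
constant SD σ and mean a polynomial in the Hazen percentile `p` of the
biomarker intake, `mu(p) = Σ m_k p^k`, with order K ∈ 1..5 chosen by
10-fold cross-validation and homoskedasticity checked by a Goldfeld-Quandt
test (central 20% discarded — 61 of 303 observations).

**Simulation.** Each of 1000 replicates resamples n = 100 rows of
(biomarkers, FFM) from the source cohort, generates self-reports from the
fitted error model and outcomes from the fitted linear model
`HO = a0 + a1 NI_BIO + N(0, η²)`, screens with the Goldberg rule, and fits
the outcome on biomarker intake, on self-report, and on the accepted
self-reports. Estimators are judged by bias, MSE (population-variance
form), and 95% CI coverage against the source-cohort slope β₁; single
cohorts are judged by percent bias `b = (β_SR − β_BIO)/β_BIO × 100` and
percent remaining bias `r = (β_G − β_BIO)/β_BIO × 100` with leave-one-out
jackknife CIs.

## Worked example

```r
library(goldbergsim)

# classify one participant: 2048 kcal/day reported, 48.9 kg fat-free mass
goldberg_classify(2048, 48.9)
#>      bmr      ee  ratio       s  lower  upper accepted
#>  1426.24 2495.92 0.8205 19.3086 0.6797 1.4713     TRUE

# a synthetic 303-person cohort calibrated to the published summaries
cohort <- generate_cohort(cohort_config(n = 303, seed = 20260928))
scr <- screen_cohort(cohort)
nrow(scr$rejected)
#> [1] 110     # 36% excluded, against 40% in the motivating cohort

# 200-replicate Monte Carlo study of the energy-body weight pair
sim <- run_simulation(cohort, sim_config(n_replicates = 200,
                                         nutrients = "ei", outcomes = "bw",
                                         seed = 2))
summarize_simulation(sim)
#>   nutrient outcome estimator      bias      mse coverage  beta1
#> 1       ei      bw       BIO -0.000184 7.73e-06    0.985 0.0141
#> 2       ei      bw        SR -0.011307 1.32e-04    0.000 0.0141
#> 3       ei      bw         G -0.008758 9.19e-05    0.335 0.0141
```

Reading the output: the biomarker estimator is essentially unbiased with
near-nominal coverage; the self-report estimator is attenuated by ~80%
(bias −0.0113 against a true slope of 0.0141 kg per kcal/day) and its CIs
never cover the truth; Goldberg screening recovers part of the slope and
part of the coverage, but nowhere near the biomarker benchmark.

## The analysis workflow

Numbered scripts under `analysis/` run the full study and write annotated
TSVs to `results/`:

1. `01_generate_cohort.R` — the calibrated synthetic source cohort.
2. `02_goldberg_screen.R` — screening and the accepted/rejected partition.
3. `03_error_models.R` — per-nutrient error-model fits and GQ checks.
4. `04_empirical_tables.R` — mean-bias tests, group comparisons, and the
   24-pair association-bias table with jackknife CIs.
5. `05_simulation_study.R` — the 1000-replicate performance study.
6. `06_sensitivity.R` — sample-size, σ-scale, and η-scale grids.

`vignettes/goldberg-cutoffs-and-reporting-bias.Rmd` documents the models,
calibration choices, and limitations.

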