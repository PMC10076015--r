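#!/usr/bin/env Rscript
# Sensitivity of the simulation conclusions to the replicate sample size
# (n = 50, 100, 200, 300), the reporting-error SD multiplier sigma_scale,
# and the outcome-noise multiplier eta_scale. Run at 250 replicates per
# setting for the energy-body weight pair, where attenuation is strongest.

library(goldbergsim)

seed <- 20261001
cohort <- read_cohort("results/cohort.csv")

run_one <- function(n, sigma_scale = 1, eta_scale = 1, tag) {
  cfg <- sim_config(n_individuals = n, n_replicates = 250,
                    nutrients = "ei", outcomes = "bw",
                    sigma_scale = sigma_scale, eta_scale = eta_scale,
                    seed = seed + n + round(1000 * sigma_scale) +
                      round(100 * eta_scale))
  perf <- summarize_simulation(run_simulation(cohort, cfg))
  cbind(setting = tag, n = n, sigma_scale = sigma_scale,
        eta_scale = eta_scale, perf)
}

grid <- list()
for (n in c(50, 100, 200, 300))
  grid[[paste0("n", n)]] <- run_one(n, tag = "sample_size")
for (ss in c(0.25, 0.5, 2, 4))
  grid[[paste0("s", ss)]] <- run_one(100, sigma_scale = ss, tag = "sigma_scale")
for (es in c(0.5, 2, 4))
  grid[[paste0("e", es)]] <- run_one(100, eta_scale = es, tag = "eta_scale")
sens <- do.call(rbind, grid)
rownames(sens) <- NULL

cat("Self-report bias for energy-body weight by setting:\n")
sub <- sens[sens$estimator == "SR", ]
for (i in seq_len(nrow(sub)))
  cat(sprintf("  %-11s n=%3d sigma x%-4g eta x%-4g  bias = %+8.5f (beta1 = %.4f)\n",
              sub$setting[i], sub$n[i], sub$sigma_scale[i], sub$eta_scale[i],
              sub$bias[i], sub$beta1[i]))
cat("Attenuation persists across sample sizes and eta; shrinking sigma\n")
cat("flips the bias positive (scale compression by the decreasing mean-error\n")
cat("function dominates once the random error is small).\n")

write_results(list(sensitivity = sens), "results", seed = seed)
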