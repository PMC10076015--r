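#!/usr/bin/env Rscript
# Apply the Goldberg cutoffs to the synthetic cohort: predicted energy
# expenditure from fat-free mass (PAL 1.75), plausibility bounds
# exp(+-2S/100) on the reported-intake:expenditure ratio, and the
# accepted/rejected partition. Writes the per-participant classification.

library(goldbergsim)

cohort <- read_cohort("results/cohort.csv")
params <- goldberg_params()
scr <- screen_cohort(cohort, params)

print(params)
cat(sprintf("Accepted %d, rejected %d of %d participants (%.1f%% excluded)\n",
            nrow(scr$accepted), nrow(scr$rejected), nrow(cohort),
            100 * nrow(scr$rejected) / nrow(cohort)))

screened <- cbind(cohort, scr$results)
write_results(list(screened_cohort = screened), "results",
              config = params)
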