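# Building a cohort_config runs the truncation-aware calibration pilot, so
# share one default config across the suite.
.cfg_cache <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(.cfg_cache$cfg)) .cfg_cache$cfg <- cohort_config()
  .cfg_cache$cfg
}

make_cohort <- function(n, seed) {
  set.seed(seed)
  generate_cohort(default_config(), n = n)
}

nutrients4 <- c("ei", "si", "poi", "pri")
outcomes6 <- c("bw", "wc", "hr", "sbp", "dbp", "vo2")

bio_col <- function(nu) c(ei = "ei_bio_kcal", si = "si_bio_mg",
                          poi = "poi_bio_mg", pri = "pri_bio_g")[[nu]]
sr_col <- function(nu) c(ei = "ei_sr_kcal", si = "si_sr_mg",
                         poi = "poi_sr_mg", pri = "pri_sr_g")[[nu]]
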