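#!/usr/bin/env Rscript
# VEP suppression analysis across the simulated cohort: 6 LGN-sonication
# and 5 active-sham experiments, each with Baseline / LGN / Control blocks
# (4 sections per sonication block here; the acceptance suite runs the
# full-length 250-trial version). Quantifies light-only N70/P100
# peak-to-peak amplitudes, normalizes to baseline, and runs the planned
# one-tailed comparisons.

library(tusvep)
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- study_config(seed = 201, n_sections = 4, n_keep = 60)
res <- run_study(cfg, file.path(out, "study"), spectra = FALSE)

norm <- res$vep_norm
cat("normalized peak-to-peak by block and group:\n")
print(aggregate(p2p_norm ~ block + group, norm, function(v)
  round(c(mean = mean(v), sd = sd(v)), 3)))

lgn <- norm[norm$block == "LGN1" & norm$group == "LGN-TUS", "p2p_norm"]
cat(sprintf("\nmean LGN-block suppression: %.0f%% of baseline (n=%d)\n",
            100 * mean(lgn), length(lgn)))
cat("\nplanned comparisons:\n")
print(res$ttests, digits = 4)
cat("\nlaterality (%% reduction ipsi vs contra):\n")
print(res$laterality, digits = 3)
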