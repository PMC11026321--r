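#!/usr/bin/env Rscript
# Synthetic participants for both designs.
#
# Generates full trial-level event logs with the two-component heuristic
# (direction base eccentricity 0.25, amplitude gain 0.5, hysteresis 0.3,
# context rate 0.1, click noise 0.07) at the studies' sample sizes:
# 36 participants for the first design, 45 for the second.

suppressPackageStartupMessages(library(scrollclick))
dir.create("results", showWarnings = FALSE)

seed <- 20260101L

for (spec in list(list(exp = "exp1", n = 36), list(exp = "exp2", n = 45))) {
  design <- switch(spec$exp,
    exp1 = generate_exp1_design(spec$n, seed = derive_seed(seed, "design_exp1")),
    exp2 = generate_exp2_design(spec$n, seed = derive_seed(seed, "design_exp2"))
  )
  ds <- generate_dataset(design, strategy = "heuristic",
                         seed = derive_seed(seed, paste0("sim_", spec$exp)))
  out <- sprintf("results/trial_logs_%s.csv", spec$exp)
  write_trial_logs(ds$events, out, manifest = ds$manifest)
  cat(sprintf("%s: %d participants, %d trials, %d events -> %s\n",
              spec$exp, spec$n, nrow(design), nrow(ds$events), out))
}
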