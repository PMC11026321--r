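#!/usr/bin/env Rscript
# Simulation-based power analyses for both designs.
#
# First design: participants behave like the minimal-trajectory model plus
# independent Gaussian noise (SD 0.20 and 0.40 screen heights), one data
# point per cell; power of the GG-corrected two-way ANOVA effects across
# sample sizes 18-36.
#
# Second design: surrogate test-trial model (means +/-0.28 about the screen
# centre, trial SD 0.07) with an inducer-eccentricity effect growing
# linearly within blocks to 0.01 or 0.03 units per adjacent level; power of
# the target x eccentricity interaction (and the three-way term with
# subblock) across sample sizes 6-48.

suppressPackageStartupMessages(library(scrollclick))
dir.create("results", showWarnings = FALSE)

seed <- 20260101L
reps <- 500

p1 <- exp1_power_sim(n_participants = c(18, 24, 30, 36),
                     noise_sd = c(0.20, 0.40),
                     n_reps = reps, seed = derive_seed(seed, "power1"))
write.csv(p1, "results/power_exp1.csv", row.names = FALSE)
cat("First design (percent of significant replicates):\n")
p1$power <- 100 * p1$power
print(p1[, c("n", "noise_sd", "effect", "power")], digits = 3)

p2 <- exp2_power_sim(n_participants = seq(6, 48, by = 6),
                     effect_size = c(0.01, 0.03),
                     n_reps = reps, seed = derive_seed(seed, "power2"))
write.csv(p2, "results/power_exp2.csv", row.names = FALSE)
cat("\nSecond design:\n")
p2$power <- 100 * p2$power
print(p2[, c("n", "effect_size", "effect", "power")], digits = 3)

cat("\nReading the tables: with SD 0.20 every first-design effect is at",
    "\nceiling for all probed sample sizes; with SD 0.40 all effects clear 95%",
    "\nfrom 24 participants on. The second design's interaction reaches 95%",
    "\npower at 12 participants for the 0.03-unit effect and 36 for 0.01.\n")
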