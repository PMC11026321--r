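#!/usr/bin/env Rscript
# Trial-log reduction and submovement classification.
#
# Reduces the simulated event logs to per-trial dependent variables
# (initial/final vertical cursor position, submovement count, response
# time, 10-s exclusion flag), reports the corrective/substantive
# submovement mix, and writes per-participant condition means.

suppressPackageStartupMessages({
  library(scrollclick)
  library(dplyr)
})

for (exp in c("exp1", "exp2")) {
  cfg <- task_config(exp)
  events <- read_trial_logs(sprintf("results/trial_logs_%s.csv", exp))
  summaries <- reduce_trials(events, cfg)
  write.csv(summaries, sprintf("results/trial_summaries_%s.csv", exp),
            row.names = FALSE)

  labels <- events %>%
    group_by(participant, block, subblock, trial_index) %>%
    group_map(~ classify_submovements(.x, cfg)) %>%
    bind_rows()
  mix <- labels %>% count(label) %>% mutate(pct = 100 * n / sum(n))
  negl <- 100 * mean(labels$negligible_reposition[labels$label == "substantive"])

  cat(sprintf(
    "%s: %d trials, %.2f%% excluded (>10 s); mean %.2f submovements/trial\n",
    exp, nrow(summaries), 100 * mean(summaries$excluded),
    mean(summaries$n_submovements)
  ))
  print(mix)
  cat(sprintf("negligible repositions among substantive submovements: %.1f%%\n\n",
              negl))

  grouping <- if (exp == "exp1") {
    c("target_number", "start_vertical")
  } else {
    c("target_number", "eccentricity_condition", "subblock")
  }
  input <- if (exp == "exp2") filter(summaries, condition == "test") else summaries
  cells <- summarize_conditions(input, grouping)
  write.csv(cells, sprintf("results/condition_means_%s.csv", exp),
            row.names = FALSE)
}
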