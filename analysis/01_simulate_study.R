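#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study — 22 tryptophan-depleted (TD) and
# 22 control (BAL) subjects, each completing 201 trials of the reward task
# and 201 trials of the punishment task (3 sessions per valence, 70/30
# transitions, outcome probabilities drifting in [0.25, 0.75]).
#
# Writes results/trials.csv (+ sidecar true parameters) and a per-valence
# outcome-schedule audit.

library(twostepRL)

seed <- 20260918L
dir.create("results", showWarnings = FALSE)

configs <- list(reward = task_config("reward"),
                punishment = task_config("punishment"))
specs <- default_group_specs()

datasets <- simulate_group_study(specs$TD, specs$BAL, configs, seed = seed)
write_subjects_csv(datasets, "results/trials.csv")

for (v in names(configs)) {
  write_schedule_csv(make_outcome_schedule(configs[[v]], derive_seed(seed, 500L)),
                     sprintf("results/schedule_audit_%s.csv", v))
  task_config_json(configs[[v]], sprintf("results/task_config_%s.json", v))
}

subjects <- attr(datasets, "subjects")
cat(sprintf("Simulated %d subjects (%s) x 2 valences, %d trials each.\n",
            nrow(subjects), paste(table(subjects$group), collapse = " + "),
            configs$reward$n_trials))
cat("Trial logs in results/trials.csv; true parameters in the .params.json sidecar.\n")
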