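#!/usr/bin/env Rscript
# Stage 6: validation harnesses. Parameter recovery — draw hybrid parameters
# from broad ranges, simulate both valences, refit jointly, tabulate
# correlation/bias/RMSE per parameter. Model recovery — cohorts generated
# under each candidate model, BMS per cohort, confusion matrix. Scaled to
# 60 subjects / 1 cohort per model here to keep the driver a few minutes;
# the acceptance suite runs the full 100-subject version.

library(twostepRL)

cfg <- study_config()

rec <- run_parameter_recovery(cfg, n_subjects = 60, seed = 77L)
write.csv(rec, "results/parameter_recovery.csv", row.names = FALSE)
cat("Parameter recovery (60 subjects, 2 x 201 trials each):\n")
print(rec, digits = 3)

mr <- run_model_recovery(cfg, n_subjects = 20, n_cohorts = 1, seed = 78L)
cat("\nModel recovery confusion matrix (rows = generator, cols = winner):\n")
print(mr$confusion)
write.csv(as.data.frame.matrix(mr$confusion), "results/model_recovery.csv")
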