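#!/usr/bin/env Rscript
# Stage 4: group-level random-effects model selection. For each group and
# task valence, the per-subject BIC log-evidences of Q-SARSA and the hybrid
# model enter the variational Dirichlet scheme; the exceedance probability is
# the posterior probability that a model is the most frequent in the
# population.

library(twostepRL)

fits <- read.csv("results/fits.csv")
out <- list()
for (v in unique(fits$valence)) {
  for (g in unique(fits$group)) {
    sub <- fits[fits$valence == v & fits$group == g, ]
    le <- reshape(sub[, c("subject_id", "model", "log_evidence")],
                  idvar = "subject_id", timevar = "model", direction = "wide")
    m <- as.matrix(le[, -1])
    colnames(m) <- sub("^log_evidence\\.", "", colnames(m))
    bms <- bms_random_effects(m, seed = 99L)
    out[[paste(g, v, sep = "_")]] <- list(
      dirichlet_alpha = bms$dirichlet_alpha,
      expected_frequency = bms$expected_frequency,
      exceedance_probability = bms$exceedance_probability,
      n_subjects = bms$n_subjects)
    cat(sprintf("%-16s exceedance: %s\n", paste(g, v, sep = "/"),
                paste(sprintf("%s = %.3f", names(bms$exceedance_probability),
                              bms$exceedance_probability), collapse = ", ")))
  }
}
jsonlite::write_json(out, "results/bms.json", auto_unbox = TRUE, digits = NA)
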