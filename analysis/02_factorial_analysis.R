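#!/usr/bin/env Rscript
# Stage 2: factorial stay/shift analysis. Stay probabilities at the first
# stage are tabulated by previous outcome (better/worse) x previous
# transition (common/rare), arcsine-transformed, and entered into
# mixed-design ANOVAs: the four-way valence x outcome x transition x group
# design, per-valence three-way designs, and per-group post hocs whose
# outcome / outcome-x-transition pattern classifies each group's strategy.

library(twostepRL)

datasets <- read_subjects_csv("results/trials.csv")
stay <- lapply(datasets, compute_stay_table)
long <- stay_long_table(stay)
write.csv(long, "results/stay_long.csv", row.names = FALSE)
if (length(attr(long, "excluded")))
  cat("Excluded (empty cells):", attr(long, "excluded"), "\n")

fourway <- mixed_anova(long, "stay_p_arcsine", "subject_id",
                       within = c("valence", "outcome_cat", "transition"),
                       between = "group")
write.csv(fourway, "results/anova_fourway.csv", row.names = FALSE)
cat("Four-way mixed ANOVA (arcsine stay probabilities):\n")
print(fourway, digits = 3)

classification <- list()
for (v in c("reward", "punishment")) {
  dv <- long[long$valence == v, ]
  av <- mixed_anova(dv, "stay_p_arcsine", "subject_id",
                    within = c("outcome_cat", "transition"), between = "group")
  write.csv(av, sprintf("results/anova_%s.csv", v), row.names = FALSE)
  for (g in unique(dv$group)) {
    ag <- mixed_anova(dv[dv$group == g, ], "stay_p_arcsine", "subject_id",
                      within = c("outcome_cat", "transition"))
    cls <- classify_signature(ag)
    classification[[paste(g, v, sep = "_")]] <- cls
    write.csv(ag, sprintf("results/anova_%s_%s.csv", g, v), row.names = FALSE)
  }
}
jsonlite::write_json(classification, "results/classification.json",
                     auto_unbox = TRUE)
cat("\nStrategy classification (outcome effect vs outcome x transition):\n")
for (k in names(classification)) cat(sprintf("  %-16s %s\n", k, classification[[k]]))

# cumulative learning: groups should not differ in either valence
cum <- do.call(rbind, lapply(datasets, function(d)
  data.frame(subject_id = d$subject_id, group = d$group, valence = d$valence,
             cumulative = cumulative_outcome(d))))
write.csv(cum, "results/cumulative.csv", row.names = FALSE)
for (v in c("reward", "punishment")) {
  cv <- cum[cum$valence == v, ]
  f <- anova(lm(cumulative ~ group, cv))
  cat(sprintf("Cumulative outcome, %s: group F(1,%d) = %.2f, p = %.2f\n",
              v, f$Df[2], f$`F value`[1], f$`Pr(>F)`[1]))
}
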