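#!/usr/bin/env Rscript
# Stage 3 — oxidative-stress and neurotoxicity biomarkers.
#
# Group means +/- SE, percent change vs control, one-way ANOVA and Tukey
# HSD with compact letters for each analyte (MDA, GSH, CAT, AChE).

library(clamtox)

biomarkers <- read_table("results/data/biomarkers.csv", "biomarkers")
res <- analyte_tests(biomarkers, control_group = "0", alpha = 0.05)

write_table(res$anova, "results/biomarker_anova.csv")
write_table(res$tukey, "results/biomarker_tukey.csv")
write_table(res$effects, "results/biomarker_effects.csv")

cat("Biomarker effects (percent change vs control):\n")
eff <- res$effects[res$effects$group != "0", ]
for (r in seq_len(nrow(eff))) {
  cat(sprintf("  %-4s %s ug/L: %s (letters %s)\n",
              eff$parameter[r], eff$group[r],
              percent_change_label(eff$percent_change[r]), eff$letters[r]))
}
cat("\nANOVA F by analyte:\n")
f <- res$anova[res$anova$source == "Between groups", c("parameter", "F", "p")]
print(f, row.names = FALSE)
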