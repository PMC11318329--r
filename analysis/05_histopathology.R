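#!/usr/bin/env Rscript
# Stage 5 — semi-quantitative and quantitative histopathology.
#
# Weighted condition index per individual (seven lesion categories, weights
# 1-3, scores 0/2/4/6, denominator 78) with low/moderate/high severity
# classes, tubule lumen/wall percentages averaged over each animal's five
# tubules, and ANOVA + Tukey across groups for both.

library(clamtox)

lesions <- read_table("results/data/lesions.csv", "lesions")
morpho <- read_table("results/data/morphometry.csv", "morphometry")

idx <- condition_index_table(lesions)
idx_sum <- group_index_summary(idx)
morph <- morphometry_summary(morpho)

write_table(idx, "results/condition_index.csv")
write_table(idx_sum, "results/condition_index_summary.csv")
write_table(morph$groups, "results/morphometry_summary.csv")

histo_long <- rbind(
  data.frame(group = idx$group, analyte = "condition_index", value = idx$Ih),
  data.frame(group = morph$individuals$group, analyte = "rel_lumen_pct",
             value = morph$individuals$rel_lumen_pct),
  data.frame(group = morph$individuals$group, analyte = "rel_wall_pct",
             value = morph$individuals$rel_wall_pct)
)
res <- analyte_tests(histo_long, control_group = "0", alpha = 0.05)
write_table(res$anova, "results/histo_anova.csv")
write_table(res$tukey, "results/histo_tukey.csv")

cat("Condition index by group (mean +/- SE, severity class):\n")
print(idx_sum, row.names = FALSE)
cat("\nRelative tubule areas by group:\n")
print(morph$groups, row.names = FALSE)
cat("\nANOVA F:\n")
print(res$anova[res$anova$source == "Between groups",
                c("parameter", "F", "p")], row.names = FALSE)
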