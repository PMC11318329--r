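#!/usr/bin/env Rscript
# Stage 4 — comet-assay DNA damage.
#
# Per-cell endpoints (tail length, tail DNA %, extent tail moment, tailed
# flag at the 5% tail-DNA cutoff) from the one-dimensional intensity
# profiles, summarised per individual and group, then ANOVA + Tukey across
# groups for each endpoint.

library(clamtox)

cells <- read_table("results/data/comet_cells.csv", "comet_cells")
metrics <- comet_metrics_table(cells, background = 0, tailed_cutoff = 5)
summ <- comet_group_summary(metrics)

write_table(metrics, "results/comet_metrics.csv")
write_table(summ$individuals, "results/comet_individuals.csv")
write_table(summ$groups, "results/comet_summary.csv")

long <- stats::reshape(
  summ$individuals, direction = "long",
  varying = c("tailed_pct", "tail_length_um", "tail_dna_pct", "tail_moment"),
  v.names = "value", timevar = "analyte",
  times = c("tailed_pct", "tail_length_um", "tail_dna_pct", "tail_moment"))
res <- analyte_tests(long, control_group = "0", alpha = 0.05)
write_table(res$anova, "results/comet_anova.csv")
write_table(res$tukey, "results/comet_tukey.csv")

cat("Comet endpoints, group means +/- SE over individuals:\n")
print(summ$groups, row.names = FALSE)
cat("\nANOVA F by endpoint:\n")
print(res$anova[res$anova$source == "Between groups",
                c("parameter", "F", "p")], row.names = FALSE)
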