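#!/usr/bin/env Rscript
# Stage 2 — survival analysis.
#
# Product-limit curves per exposure group and the k-group log-rank test on
# the pooled records (individuals are pooled across replicate aquaria; the
# design is too small to model inter-aquarium frailty).

library(clamtox)

records <- read_table("results/data/survival.csv", "survival")

km <- km_curves(records)
lr <- logrank_test(records)
mort <- mortality_summary(records)

write_table(km, "results/km_curves.csv")
write_table(mort, "results/mortality.csv")
jsonlite::write_json(
  list(chisq = lr$chisq, df = lr$df, p_value = lr$p_value,
       observed = as.list(lr$observed), expected = as.list(lr$expected)),
  "results/logrank.json", auto_unbox = TRUE, digits = 10)

print(lr)
print(mort)
cat("\nSurvival at day 21 by group:\n")
for (g in unique(records$group)) {
  cat(sprintf("  %s ug/L: S(21) = %.3f\n", g,
              km_survival_at(km_estimate(records, g), 21)))
}
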