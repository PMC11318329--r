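#!/usr/bin/env Rscript
# Stage 6 — end-to-end report.
#
# Runs the orchestrated pipeline on the same seed as stage 1, producing the
# consolidated report.json plus all stage tables under results/report/.
# Because every stage is a pure function of (config, seed), its numbers
# agree with stages 02-05 run separately.

library(clamtox)

cfg <- default_config(seed = 20240812L)
report <- run_pipeline(cfg, "results/report", verbose = TRUE)

cat("\n--- Report highlights ---\n")
cat(sprintf("Log-rank: chi-square %.2f, df %d, p = %.3f\n",
            report$survival$logrank$chisq, report$survival$logrank$df,
            report$survival$logrank$p_value))
mort <- report$survival$mortality
cat(sprintf("Mortality: %s\n",
            paste(sprintf("%s ug/L %.0f%%", mort$group, mort$mortality_pct),
                  collapse = ", ")))
idx <- report$histopathology$condition_index
cat(sprintf("Condition index: %s\n",
            paste(sprintf("%s ug/L %.2f (%s)", idx$group, idx$mean_Ih, idx$class),
                  collapse = ", ")))
cat("Full report: results/report/report.json\n")
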