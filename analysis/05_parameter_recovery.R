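#!/usr/bin/env Rscript

# Step 5: parameter recovery at survey scale.
#
# Simulate repeatedly from the combined-model truth at the survey's own
# size (140 stations), refit the true structured equations, and summarise
# per-path bias and 95% Wald CI coverage. Strong landscape paths recover
# tightly even at n = 140; the weak species-on-species paths are noisy at
# this sample size, which is the expected behaviour for effects of this
# magnitude.

suppressMessages(library(camtrapSEM))
dir.create("results", showWarnings = FALSE)

rec <- parameter_recovery(default_truth(), n_stations = 140,
                          n_replicates = 200, seed = 42)
rec$rel_bias_pct <- 100 * rec$bias / abs(rec$truth)
cat("== Parameter recovery (n = 140, 200 replicates) ==\n")
print(rec[order(-abs(rec$truth)), ], row.names = FALSE, digits = 3)
cat(sprintf("\nfailed replicates: %d of %d\n", attr(rec, "n_failed"),
            attr(rec, "n_replicates")))
cat(sprintf("median |relative bias|: %.1f%%; coverage range [%.3f, %.3f]\n",
            stats::median(abs(rec$rel_bias_pct)), min(rec$coverage),
            max(rec$coverage)))
utils::write.csv(rec, "results/parameter_recovery.csv", row.names = FALSE)
cat("wrote results/parameter_recovery.csv\n")
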