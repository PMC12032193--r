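#!/usr/bin/env Rscript

# Step 3: stepwise optimization of both a-priori models.
#
# Significant independence claims are processed in ascending-p order:
# whitelisted paths are added when they lower Fisher's C, unexplained
# species-species associations become correlated errors, and hypothesized
# paths that are non-significant with the wrong sign are pruned.

suppressMessages(library(camtrapSEM))
stopifnot(file.exists("results/synthetic_stations.csv"))
survey <- scale_covariates(read_station_table("results/synthetic_stations.csv"))

opt_td <- optimize_sem(spec_topdown(), survey)
opt_bu <- optimize_sem(spec_bottomup(), survey)

cat("== Top-down optimization trace ==\n")
print(opt_td$trace)
cat("\n== Bottom-up optimization trace ==\n")
print(opt_bu$trace)

for (m in list(list("topdown", opt_td), list("bottomup", opt_bu))) {
  write_sem_spec(m[[2]]$spec, sprintf("results/optimized_%s.json", m[[1]]))
  st <- m[[2]]$trace$steps
  utils::write.csv(st, sprintf("results/trace_%s.csv", m[[1]]),
                   row.names = FALSE)
}

reports <- list(top_down = sem_fit(opt_td$spec, survey),
                bottom_up = sem_fit(opt_bu$spec, survey))
cat("\n== Optimized model fit ==\n")
print(compare_models(reports))
write_gof_csv(reports, "results/optimized_gof.csv")
cat("\nwrote results/optimized_{topdown,bottomup}.json, trace_*.csv,",
    "optimized_gof.csv\n")
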